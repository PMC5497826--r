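# Independent ASDF (SQZ/DIF/DUP) reference encoder, written directly from
# the published pseudo-digit tables. Used as the oracle for the package's
# decoder; deliberately shares no code with it.

asdf_sqz <- function(v) {
  digits <- as.character(abs(v))
  first <- substr(digits, 1, 1)
  map_pos <- c(`0` = "@", `1` = "A", `2` = "B", `3` = "C", `4` = "D",
               `5` = "E", `6` = "F", `7` = "G", `8` = "H", `9` = "I")
  map_neg <- c(`0` = "@", `1` = "a", `2` = "b", `3` = "c", `4` = "d",
               `5` = "e", `6` = "f", `7` = "g", `8` = "h", `9` = "i")
  head_c <- if (v < 0) map_neg[first] else map_pos[first]
  paste0(head_c, substr(digits, 2, nchar(digits)))
}

asdf_dif <- function(d) {
  digits <- as.character(abs(d))
  first <- substr(digits, 1, 1)
  map_pos <- c(`0` = "%", `1` = "J", `2` = "K", `3` = "L", `4` = "M",
               `5` = "N", `6` = "O", `7` = "P", `8` = "Q", `9` = "R")
  map_neg <- c(`0` = "%", `1` = "j", `2` = "k", `3` = "l", `4` = "m",
               `5` = "n", `6` = "o", `7` = "p", `8` = "q", `9` = "r")
  head_c <- if (d < 0) map_neg[first] else map_pos[first]
  paste0(head_c, substr(digits, 2, nchar(digits)))
}

asdf_dup <- function(count) {
  # count = total number of occurrences of the preceding item
  digits <- as.character(count)
  map <- c(`1` = "S", `2` = "T", `3` = "U", `4` = "V", `5` = "W",
           `6` = "X", `7` = "Y", `8` = "Z", `9` = "s")
  paste0(map[substr(digits, 1, 1)], substr(digits, 2, nchar(digits)))
}

# Encode an integer vector as one DIFDUP line starting at abscissa x.
asdf_encode_line <- function(x, y) {
  out <- paste0(format(x), asdf_sqz(y[1]))
  d <- diff(y)
  i <- 1L
  while (i <= length(d)) {
    run <- 1L
    while (i + run <= length(d) && d[i + run] == d[i]) run <- run + 1L
    out <- paste0(out, asdf_dif(d[i]))
    if (run > 1L) out <- paste0(out, asdf_dup(run))
    i <- i + run
  }
  out
}
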