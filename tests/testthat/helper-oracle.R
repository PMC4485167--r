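# Independent Code 39 oracle, deliberately built by a different route than
# the package table: the decade construction of the symbology (a wide-bar
# pair sequence repeated per decade, with the wide space cycling s2, s3,
# s4, s1, and the four symbol characters carrying three wide spaces and no
# wide bars).  Used to cross-check encoding and as an independent decoder
# on clean renders (no third-party Code 39 reader exists in this
# environment).

oracle_code39_table <- function() {
  bar_seq <- c("10001", "01001", "11000", "00101", "10100",
               "01100", "00011", "10010", "01010", "00110")
  decades <- list(
    list(chars = c("1","2","3","4","5","6","7","8","9","0"), space = "0100"),
    list(chars = LETTERS[1:10],  space = "0010"),
    list(chars = LETTERS[11:20], space = "0001"),
    list(chars = c(LETTERS[21:26], "-", ".", " ", "*"), space = "1000")
  )
  out <- character(0)
  for (d in decades) {
    for (i in seq_along(d$chars)) {
      b <- strsplit(bar_seq[i], "")[[1]]
      s <- strsplit(d$space, "")[[1]]
      inter <- c(rbind(b[1:4], s), b[5])
      out[d$chars[i]] <- paste(ifelse(inter == "1", "W", "N"), collapse = "")
    }
  }
  sym <- c("$" = "1110", "/" = "1101", "+" = "1011", "%" = "0111")
  for (ch in names(sym)) {
    s <- strsplit(sym[[ch]], "")[[1]]
    inter <- c(rbind(rep("0", 4), s), "0")
    out[ch] <- paste(ifelse(inter == "1", "W", "N"), collapse = "")
  }
  out
}

# minimal independent decoder for clean, full-contrast renders: single scan
# row, midpoint threshold, exact run lengths, nearest-width classification
oracle_decode <- function(img) {
  v <- img[ceiling(nrow(img) / 2), ]
  thr <- (min(v) + max(v)) / 2
  r <- rle(v < thr)
  runs <- data.frame(dark = r$values, len = r$lengths)
  while (nrow(runs) && !runs$dark[1]) runs <- runs[-1, ]
  while (nrow(runs) && !runs$dark[nrow(runs)]) runs <- runs[-nrow(runs), ]
  n <- nrow(runs)
  if (n %% 10L != 9L) return(NA_character_)
  narrow <- min(runs$len)
  cls <- ifelse(runs$len > 2 * narrow, "W", "N")
  tab <- oracle_code39_table()
  k <- (n + 1L) %/% 10L
  chars <- vapply(seq_len(k), function(i) {
    pat <- paste(cls[(10L * (i - 1L) + 1L):(10L * (i - 1L) + 9L)],
                 collapse = "")
    hit <- names(tab)[match(pat, tab)]
    if (length(hit)) hit else NA_character_
  }, character(1))
  if (anyNA(chars) || chars[1] != "*" || chars[k] != "*") return(NA_character_)
  paste(chars[-c(1L, k)], collapse = "")
}

# run table of alternating dark/light run lengths for a framed character
# sequence (narrow 10 px, wide 30 px), for decoder unit tests
runs_from_chars <- function(chars, patterns = NULL, lead = 200L,
                            trail = 200L) {
  tab <- oracle_code39_table()
  lens <- integer(0); dark <- logical(0)
  for (i in seq_along(chars)) {
    pat <- if (is.null(patterns)) tab[[chars[i]]] else patterns[i]
    w <- ifelse(strsplit(pat, "")[[1]] == "W", 30L, 10L)
    lens <- c(lens, w); dark <- c(dark, rep(c(TRUE, FALSE), length.out = 9))
    if (i < length(chars)) { lens <- c(lens, 10L); dark <- c(dark, FALSE) }
  }
  runs <- data.frame(dark = dark, length = lens)
  attr(runs, "leading_light") <- lead
  attr(runs, "trailing_light") <- trail
  attr(runs, "background") <- 255
  runs
}

# deterministic sample of random payloads over the non-"*" alphabet
random_payloads <- function(n, seed = 42, max_len = 6) {
  alphabet <- setdiff(names(code39_table()), "*")
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, sample(seq_len(max_len), 1), replace = TRUE),
          collapse = ""), character(1))
}
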