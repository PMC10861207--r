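# Independent reference implementations used to check package results.
# These deliberately use naive enumeration, not the package's code paths.

# two-sample log-rank chi-square by explicit risk-set tabulation
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O1 <- E1 <- V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1)
    d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            D = "H", H = "D", W = "W", R = "Y", Y = "R")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# window-by-window membership scan of one sequence for one IUPAC motif
oracle_scan <- function(seq, motif, both_strands = TRUE) {
  seq <- toupper(seq)
  k <- nchar(motif)
  L <- nchar(seq)
  if (L < k) {
    return(data.frame(strand = character(), start = integer(),
                      matched_word = character(), stringsAsFactors = FALSE))
  }
  words_fwd <- expand_iupac(motif)
  starts <- seq_len(L - k + 1)
  windows <- substring(seq, starts, starts + k - 1)
  fwd_hit <- windows %in% words_fwd
  out <- data.frame(strand = rep("+", sum(fwd_hit)),
                    start = starts[fwd_hit] - 1L,
                    matched_word = windows[fwd_hit],
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rc_words <- vapply(words_fwd, oracle_revcomp, character(1))
    hit <- windows %in% rc_words
    out <- rbind(out, data.frame(
      strand = rep("-", sum(hit)), start = starts[hit] - 1L,
      matched_word = vapply(windows[hit], oracle_revcomp, character(1),
                            USE.NAMES = FALSE),
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# a small deterministic multi-group event table used by several tests
toy_events <- function() {
  rbind_event_tables(
    event_table(paste0("c", 1:6), "control", c(10, 12, 14, 16, 18, 20), 1),
    event_table(paste0("s", 1:6), "stress", c(3, 4, 5, 6, 7, 8), 1)
  )
}

rbind_event_tables <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  attr(out, "unit") <- attr(parts[[1]], "unit")
  class(out) <- c("event_table", "data.frame")
  out
}
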