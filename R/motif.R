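#' SKN-1/Nrf binding consensus motifs
#'
#' The two degenerate 8-mer consensus sequences used to flag putative
#' SKN-1 target promoters: `TTDTCATC` (D = A/G/T) and `WWTRTCAT`
#' (W = A/T, R = A/G).
#'
#' @return Character vector of the two IUPAC patterns.
#' @export
skn1_motifs <- function() c("TTDTCATC", "WWTRTCAT")

# degeneracy codes this scanner supports
IUPAC_SUPPORTED <- list(
  A = "A", C = "C", G = "G", T = "T",
  D = c("A", "G", "T"), W = c("A", "T"), R = c("A", "G")
)

#' Expand a degenerate IUPAC pattern to its concrete words
#'
#' Full Cartesian expansion over the supported codes A, C, G, T,
#' D = A/G/T, W = A/T, R = A/G.
#'
#' @param pattern string over the supported alphabet.
#' @return Character vector of all concrete words the pattern denotes;
#'   its length is the product of per-position degeneracies.
#' @examples
#' length(expand_iupac("TTDTCATC"))  # 3
#' length(expand_iupac("WWTRTCAT"))  # 8
#' @export
expand_iupac <- function(pattern) {
  letters_ <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters_, names(IUPAC_SUPPORTED))
  if (length(bad) > 0) {
    stop("unsupported IUPAC code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  sets <- IUPAC_SUPPORTED[letters_]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  words <- do.call(paste0, rev(grid))
  sort(unique(words))
}

# coerce scan input to a named uppercase character vector of sequences
as_sequence_set <- function(x) {
  if (inherits(x, "promoter_set")) x <- x$seqs
  if (methods::is(x, "DNAStringSet")) {
    seqs <- toupper(as.character(x))
  } else if (is.character(x)) {
    seqs <- toupper(x)
  } else {
    stop("sequences must be a character vector, DNAStringSet or promoter_set",
         call. = FALSE)
  }
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must be named by gene_id", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate gene_id in sequences: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  seqs
}

#' Scan promoter sequences for degenerate consensus motifs
#'
#' Reports every (possibly overlapping) occurrence of each motif on the
#' forward strand and, by default, on the reverse strand (found by
#' matching the reverse-complemented motif against the forward sequence).
#' Matching is case-insensitive; `N` or any other ambiguity code in the
#' subject sequence never matches. Coordinates are 0-based half-open
#' offsets on the provided sequence; `matched_word` is the site as read on
#' its own strand, so it always belongs to the motif's expansion.
#'
#' @param promoters named character vector, `DNAStringSet`, or
#'   [extract_promoters()] result; names are gene ids.
#' @param motifs character vector of IUPAC patterns
#'   (default [skn1_motifs()]).
#' @param both_strands scan the reverse strand too (default `TRUE`).
#' @return data.frame of hits: `gene_id`, `motif`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (0-based half-open), `matched_word`; sorted by gene
#'   and start. Zero rows when nothing matches.
#' @examples
#' scan_motifs(c(g1 = "AATTATCATCAA"), "TTDTCATC")
#' @export
scan_motifs <- function(promoters, motifs = skn1_motifs(),
                        both_strands = TRUE) {
  seqs <- as_sequence_set(promoters)
  hits <- lapply(names(seqs), function(id) {
    subject <- Biostrings::DNAString(seqs[[id]])
    per_motif <- lapply(motifs, function(m) {
      scan_one(subject, id, m, both_strands)
    })
    do.call(rbind, per_motif)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), motif = character(),
                      strand = character(), start = integer(),
                      end = integer(), matched_word = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id, out$start, out$strand, out$motif), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_one <- function(subject, id, motif, both_strands) {
  k <- nchar(motif)
  if (length(subject) < k) return(NULL)
  # fixed = "subject": degeneracy codes in the pattern are interpreted,
  # letters in the subject are literal, so N never matches
  fwd <- Biostrings::matchPattern(motif, subject, fixed = "subject")
  res <- if (length(fwd) > 0) {
    data.frame(gene_id = id, motif = motif, strand = "+",
               start = Biostrings::start(fwd) - 1L,
               end = Biostrings::end(fwd),
               matched_word = as.character(fwd),
               stringsAsFactors = FALSE)
  } else NULL
  if (both_strands) {
    rc <- Biostrings::reverseComplement(Biostrings::DNAString(motif))
    rev <- Biostrings::matchPattern(rc, subject, fixed = "subject")
    if (length(rev) > 0) {
      words <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(rev))
      )
      res <- rbind(res, data.frame(
        gene_id = id, motif = motif, strand = "-",
        start = Biostrings::start(rev) - 1L,
        end = Biostrings::end(rev),
        matched_word = words,
        stringsAsFactors = FALSE
      ))
    }
  }
  res
}
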