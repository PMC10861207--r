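#' Filter a differential-expression table
#'
#' Keeps genes with `|log2fc| >= log2(fc_min)` and `fdr <= fdr_max`
#' (both thresholds inclusive; the defaults are fold change >= 2, i.e.
#' `|log2FC| >= 1`, and FDR <= 0.05) and splits them by direction of
#' regulation. Records with an FDR outside \[0, 1\] or non-finite fields
#' are rejected with a warning naming them.
#'
#' @param records data.frame with columns `gene_id`, `log2fc`, `fdr`.
#' @param fc_min minimum fold change (linear scale), default 2.
#' @param fdr_max maximum FDR, default 0.05.
#' @return List with data.frames `up` and `down`, each carrying a
#'   `direction` column; up means `log2fc > 0`.
#' @examples
#' degs <- data.frame(gene_id = c("a", "b"), log2fc = c(1, 0.99),
#'                    fdr = c(0.05, 0.001))
#' filter_degs(degs)$up$gene_id  # "a" (boundary kept, "b" below FC)
#' @export
filter_degs <- function(records, fc_min = 2, fdr_max = 0.05) {
  required <- c("gene_id", "log2fc", "fdr")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(records$log2fc) | !is.finite(records$fdr) |
    records$fdr < 0 | records$fdr > 1
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected (FDR outside [0, 1] or ",
            "non-finite fields): ",
            paste(utils::head(records$gene_id[bad], 10), collapse = ", "),
            call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }
  keep <- abs(records$log2fc) >= log2(fc_min) & records$fdr <= fdr_max
  kept <- records[keep, , drop = FALSE]
  kept$direction <- ifelse(kept$log2fc > 0, "up", "down")
  rownames(kept) <- NULL
  list(up = kept[kept$direction == "up", , drop = FALSE],
       down = kept[kept$direction == "down", , drop = FALSE])
}

#' Annotate differentially expressed genes with promoter motif sites
#'
#' Scans each gene's promoter for the given consensus motifs and reports
#' per-gene site counts. A gene without a supplied promoter is marked
#' unknown (`n_sites = NA`), never zero.
#'
#' @param degs data.frame with at least `gene_id` and `log2fc` (e.g. a
#'   component of [filter_degs()] output, or both components row-bound).
#' @param promoters named sequences as accepted by [scan_motifs()];
#'   duplicate gene ids are an error.
#' @param motifs IUPAC patterns (default [skn1_motifs()]).
#' @param both_strands passed to [scan_motifs()].
#' @return data.frame: `gene_id`, `direction`, `n_sites`, `has_site`;
#'   attribute `"summary"` holds `n_genes`, `n_known` (promoter present)
#'   and `n_with_site`.
#' @export
annotate_degs_with_sites <- function(degs, promoters,
                                     motifs = skn1_motifs(),
                                     both_strands = TRUE) {
  if (!"gene_id" %in% names(degs)) stop("degs must have gene_id", call. = FALSE)
  seqs <- as_sequence_set(promoters)
  known <- intersect(degs$gene_id, names(seqs))
  counts <- integer(0)
  if (length(known) > 0) {
    hits <- scan_motifs(seqs[known], motifs, both_strands)
    counts <- table(factor(hits$gene_id, levels = known))
  }
  n_sites <- rep(NA_integer_, nrow(degs))
  idx <- match(degs$gene_id, known)
  n_sites[!is.na(idx)] <- as.integer(counts[idx[!is.na(idx)]])
  direction <- if ("direction" %in% names(degs)) {
    degs$direction
  } else if ("log2fc" %in% names(degs)) {
    ifelse(degs$log2fc > 0, "up", "down")
  } else {
    NA_character_
  }
  out <- data.frame(gene_id = degs$gene_id, direction = direction,
                    n_sites = n_sites, has_site = n_sites >= 1,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- list(
    n_genes = nrow(out),
    n_known = sum(!is.na(out$n_sites)),
    n_with_site = sum(out$has_site, na.rm = TRUE)
  )
  out
}

#' Extract promoter regions upstream of genes
#'
#' For each gene the promoter is the `flank` bases (default 1,500)
#' immediately upstream of its 5' end: for a plus-strand gene the bases
#' ending just before the feature start; for a minus-strand gene the bases
#' beginning just after the feature end, reverse-complemented so the
#' returned sequence reads 5'->3' toward the gene. Promoters running off a
#' contig edge are truncated and flagged. Input coordinates follow the
#' annotation convention (1-based, inclusive); output coordinates are
#' 0-based half-open on the contig.
#'
#' @param genome named `DNAStringSet` or path to a FASTA file.
#' @param annotations one of: a data.frame with columns `gene_id`,
#'   `contig`, `start`, `end`, `strand` (1-based inclusive); a `GRanges`;
#'   or a path to a GFF3 file (features of type `gene` are used, gene ids
#'   taken from `ID`/`gene_id`/`Name`).
#' @param flank upstream window length in bases (default 1500).
#' @return Object of class `"promoter_set"`: list with `seqs` (named
#'   character vector of promoter sequences, 5'->3') and `coords`
#'   (data.frame `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `truncated`).
#' @export
extract_promoters <- function(genome, annotations, flank = 1500) {
  if (is.character(genome) && length(genome) == 1) {
    genome <- read_fasta(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a DNAStringSet or FASTA path", call. = FALSE)
  }
  ann <- normalize_annotations(annotations)
  if (anyDuplicated(ann$gene_id)) {
    stop("duplicate gene_id in annotations", call. = FALSE)
  }
  missing_contig <- setdiff(unique(ann$contig), names(genome))
  if (length(missing_contig) > 0) {
    bad_genes <- ann$gene_id[ann$contig %in% missing_contig]
    stop("contig(s) absent from genome for gene(s): ",
         paste(bad_genes, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    g <- ann[i, ]
    clen <- Biostrings::width(genome[g$contig])
    if (g$strand == "+") {
      p_end <- g$start - 1L              # 1-based inclusive
      p_start <- max(1L, g$start - flank)
    } else {
      p_start <- g$end + 1L
      p_end <- min(clen, g$end + flank)
    }
    if (p_end < p_start) {
      seq <- ""
      p_start <- p_end + 1L  # zero-width at the anchor
    } else {
      seq <- as.character(Biostrings::subseq(genome[[g$contig]],
                                             start = p_start, end = p_end))
      if (g$strand == "-") {
        seq <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      }
    }
    list(seq = toupper(seq),
         coord = data.frame(gene_id = g$gene_id, contig = g$contig,
                            start = p_start - 1L, end = p_end,
                            strand = g$strand,
                            truncated = nchar(seq) < flank,
                            stringsAsFactors = FALSE))
  })
  seqs <- vapply(rows, function(r) r$seq, character(1))
  names(seqs) <- ann$gene_id
  structure(list(seqs = seqs,
                 coords = do.call(rbind, lapply(rows, `[[`, "coord")),
                 flank = flank),
            class = "promoter_set")
}

normalize_annotations <- function(annotations) {
  if (is.character(annotations) && length(annotations) == 1) {
    gr <- rtracklayer::import(annotations, format = "gff3")
    gr <- gr[gr$type == "gene"]
    annotations <- gr
  }
  if (methods::is(annotations, "GRanges")) {
    meta <- GenomicRanges::mcols(annotations)
    id <- if ("ID" %in% names(meta)) meta$ID
          else if ("gene_id" %in% names(meta)) meta$gene_id
          else if ("Name" %in% names(meta)) meta$Name
          else stop("annotations lack an ID/gene_id/Name field", call. = FALSE)
    annotations <- data.frame(
      gene_id = as.character(id),
      contig = as.character(GenomicRanges::seqnames(annotations)),
      start = GenomicRanges::start(annotations),
      end = GenomicRanges::end(annotations),
      strand = as.character(GenomicRanges::strand(annotations)),
      stringsAsFactors = FALSE
    )
  }
  required <- c("gene_id", "contig", "start", "end", "strand")
  missing <- setdiff(required, names(annotations))
  if (length(missing) > 0) {
    stop("annotations missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(annotations$strand %in% c("+", "-"))) {
    stop("every gene needs strand '+' or '-'", call. = FALSE)
  }
  annotations
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("Promoter set: %d sequences (target length %d nt, %d truncated)\n",
              length(x$seqs), x$flank, sum(x$coords$truncated)))
  invisible(x)
}
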