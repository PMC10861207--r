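#' Read a subject-level survival CSV
#'
#' Expects a header with columns `subject_id`, `group`, `time`, `event`.
#' Rows with a non-numeric or negative time, or an event flag other than
#' 0/1, are rejected with an error citing their line numbers (header =
#' line 1).
#'
#' @param path file path.
#' @param unit time unit to record on the table.
#' @return An [event_table()].
#' @export
read_survival_csv <- function(path, unit = "days") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("subject_id", "group", "time", "event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(df$time))
  event <- suppressWarnings(as.integer(df$event))
  bad <- is.na(time) | time < 0 | is.na(event) | !(event %in% c(0L, 1L))
  if (any(bad)) {
    stop("malformed time/event on line(s): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
  event_table(df$subject_id, df$group, time, event, unit = unit)
}

#' Write a survival event table as CSV
#' @param events an [event_table()].
#' @param path output path.
#' @export
write_survival_csv <- function(events, path) {
  validate_event_table(events)
  utils::write.csv(as.data.frame(events)[, c("subject_id", "group", "time",
                                             "event")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read worm tracks from a long-format CSV
#'
#' Expects columns `worm_id`, `t_s`, `x_mm`, `y_mm`, one row per frame.
#'
#' @param path file path.
#' @return Named list of [worm_track()]s.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("worm_id", "t_s", "x_mm", "y_mm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  by_worm <- split(df, df$worm_id)
  tracks <- lapply(by_worm, function(d) {
    d <- d[order(d$t_s), , drop = FALSE]
    worm_track(d$worm_id[1], d$t_s, d$x_mm, d$y_mm)
  })
  tracks[unique(df$worm_id)]
}

#' Write worm tracks as a long-format CSV
#' @param tracks list of [worm_track()]s.
#' @param path output path.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "worm_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(worm_id = tr$worm_id, t_s = tr$t, x_mm = tr$x, y_mm = tr$y,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a differential-expression table (TSV)
#'
#' Expects columns `gene_id`, `log2fc`, `fdr`.
#' @param path file path.
#' @return data.frame ready for [filter_degs()].
#' @export
read_deg_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "log2fc", "fdr")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a differential-expression table (TSV)
#' @param degs data.frame with `gene_id`, `log2fc`, `fdr`.
#' @param path output path.
#' @export
write_deg_tsv <- function(degs, path) {
  utils::write.table(degs, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a FASTA file of sequences
#'
#' Sequences are uppercased; duplicate ids and empty files are errors.
#' Headers are truncated at the first whitespace to give the record id.
#'
#' @param path file path.
#' @return A `DNAStringSet` named by record id.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("FASTA file has no records: ", path,
                              call. = FALSE)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence id(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Write named sequences as FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write motif hits as BED6
#'
#' Intervals are 0-based half-open, name = motif pattern, score = 0,
#' strand from the hit; rows are stably sorted by (chrom, start).
#'
#' @param hits data.frame from [scan_motifs()].
#' @param path output path.
#' @export
write_bed <- function(hits, path) {
  required <- c("gene_id", "motif", "strand", "start", "end")
  missing <- setdiff(required, names(hits))
  if (length(missing) > 0) {
    stop("hits missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(hits) > 0 && any(hits$start < 0)) {
    stop("negative start coordinate", call. = FALSE)
  }
  bed <- data.frame(chrom = hits$gene_id, start = hits$start, end = hits$end,
                    name = hits$motif, score = rep(0L, nrow(hits)),
                    strand = hits$strand, stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6 file of motif hits
#' @param path file path.
#' @return data.frame `gene_id`, `start`, `end`, `motif`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      score = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", "start", "end", "motif", "score", "strand")
  df
}

#' Read a fitness-panel CSV
#'
#' Long format: columns `group`, `metric`, `value` and optionally `n`;
#' metrics must cover [FITNESS_METRICS].
#'
#' @param path file path.
#' @return Named list of [fitness_panel()]s, one per group.
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("group", "metric", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$group)[unique(df$group)], function(d) {
    missing_m <- setdiff(FITNESS_METRICS, d$metric)
    if (length(missing_m) > 0) {
      stop("group '", d$group[1], "' missing metric(s): ",
           paste(missing_m, collapse = ", "), call. = FALSE)
    }
    v <- stats::setNames(d$value, d$metric)
    fitness_panel(d$group[1], v[["body_size"]], v[["crawl_speed"]],
                  v[["direction_index"]], v[["swim_speed"]],
                  v[["thrash_freq"]])
  })
}
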