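# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a survival cohort
#'
#' Draws death times from an exponential or Gompertz law. The Gompertz
#' hazard is parameterized as `h(t) = a * exp(b * t)` (baseline hazard
#' `a`, ageing rate `b`); `b = 0` recovers the exponential with rate `a`.
#' Times beyond `max_follow_up` are censored at the horizon.
#'
#' @param n cohort size (>= 1).
#' @param model `"exponential"` or `"gompertz"`.
#' @param rate exponential hazard (required for the exponential model).
#' @param a,b Gompertz parameters (`a > 0`, `b >= 0`).
#' @param max_follow_up optional censoring horizon.
#' @param seed mandatory integer seed; identical specs and seeds give
#'   identical tables.
#' @param group group label for the resulting table.
#' @param unit time unit label.
#' @return An [event_table()].
#' @examples
#' et <- simulate_cohort(100, rate = 0.1, seed = 1)
#' mean(et$time)  # about 10
#' @export
simulate_cohort <- function(n, model = c("exponential", "gompertz"),
                            rate = NULL, a = NULL, b = NULL,
                            max_follow_up = NULL, seed, group = "cohort",
                            unit = "days") {
  model <- match.arg(model)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  times <- with_seed(seed, {
    if (model == "exponential") {
      if (is.null(rate) || rate <= 0) stop("rate must be positive", call. = FALSE)
      stats::rexp(n, rate = rate)
    } else {
      if (is.null(a) || a <= 0) stop("Gompertz a must be positive", call. = FALSE)
      if (is.null(b) || b < 0) stop("Gompertz b must be nonnegative", call. = FALSE)
      u <- stats::runif(n)
      if (b == 0) -log(u) / a else log1p(-b * log(u) / a) / b
    }
  })
  event <- rep(1L, n)
  if (!is.null(max_follow_up)) {
    cens <- times > max_follow_up
    times[cens] <- max_follow_up
    event[cens] <- 0L
  }
  event_table(sprintf("%s_%04d", group, seq_len(n)), group, times, event,
              unit = unit)
}

#' Simulate worm centroid tracks with known ground truth
#'
#' Motile worms follow a correlated random walk: the heading evolves by
#' wrapped-normal increments with occasional Poisson-timed reversals
#' (instantaneous 180-degree flips plus small noise), and per-frame speeds
#' are drawn around `motile_speed_mean`. Paralyzed worms jitter in place
#' with speeds near `paralyzed_speed_mean`, far below the paralysis
#' threshold. The number of paralyzed animals is `round(paralyzed_fraction
#' * n_worms)`, assigned at random. Truth labels (paralysis status and
#' reversal counts) are returned for recovery tests.
#'
#' @param n_worms number of animals.
#' @param duration recording length (s); the assay default is a 30-s video.
#' @param fps frames per second.
#' @param motile_speed_mean,motile_speed_sd per-frame speed law for motile
#'   worms (mm/s).
#' @param paralyzed_speed_mean mean jitter speed of paralyzed worms (mm/s);
#'   keep well below 0.015.
#' @param reversal_rate Poisson rate of heading reversals (events/s).
#' @param paralyzed_fraction fraction of animals paralyzed, in \[0, 1\].
#' @param heading_sd per-frame wrapped-normal heading increment (radians).
#' @param seed mandatory integer seed.
#' @return List with `tracks` (list of [worm_track()]) and `truth`
#'   (data.frame `worm_id`, `paralyzed`, `n_reversals`).
#' @export
simulate_tracks <- function(n_worms = 30, duration = 30, fps = 2,
                            motile_speed_mean = 0.12,
                            motile_speed_sd = 0.03,
                            paralyzed_speed_mean = 0.002,
                            reversal_rate = 0.2,
                            paralyzed_fraction = 0,
                            heading_sd = 0.15, seed) {
  if (paralyzed_fraction < 0 || paralyzed_fraction > 1) {
    stop("paralyzed_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (fps <= 0 || duration <= 0) stop("fps and duration must be positive",
                                      call. = FALSE)
  if (motile_speed_mean < 0 || paralyzed_speed_mean < 0) {
    stop("speeds must be nonnegative", call. = FALSE)
  }
  with_seed(seed, {
    dt <- 1 / fps
    t <- seq(0, duration, by = dt)
    n_steps <- length(t) - 1
    n_par <- round(paralyzed_fraction * n_worms)
    is_par <- rep(FALSE, n_worms)
    is_par[sample.int(n_worms, n_par)] <- TRUE
    tracks <- vector("list", n_worms)
    n_rev <- integer(n_worms)
    for (i in seq_len(n_worms)) {
      id <- sprintf("worm_%04d", i)
      if (is_par[i]) {
        step_len <- abs(stats::rnorm(n_steps, paralyzed_speed_mean,
                                     paralyzed_speed_mean / 4)) * dt
        theta <- stats::runif(n_steps, 0, 2 * pi)
      } else {
        rev_here <- stats::rbinom(n_steps, 1, min(1, reversal_rate * dt))
        n_rev[i] <- sum(rev_here)
        dtheta <- stats::rnorm(n_steps, 0, heading_sd) +
          rev_here * (pi + stats::rnorm(n_steps, 0, 0.05))
        theta <- cumsum(c(stats::runif(1, 0, 2 * pi), dtheta))[-1]
        speed <- pmax(stats::rnorm(n_steps, motile_speed_mean,
                                   motile_speed_sd),
                      motile_speed_mean / 4)
        step_len <- speed * dt
      }
      x <- cumsum(c(0, step_len * cos(theta)))
      y <- cumsum(c(0, step_len * sin(theta)))
      tracks[[i]] <- worm_track(id, t, x, y, fps = fps)
    }
    list(tracks = tracks,
         truth = data.frame(worm_id = sprintf("worm_%04d", seq_len(n_worms)),
                            paralyzed = is_par, n_reversals = n_rev,
                            stringsAsFactors = FALSE))
  })
}

#' Generate promoters with planted motif sites and a matching DE table
#'
#' Background promoters are i.i.d. nucleotide sequences at the requested
#' GC content (the default 0.36 approximates the C. elegans genome). A
#' chosen fraction of genes receives `sites_per_planted` concrete motif
#' words inserted at non-overlapping uniform positions on random strands.
#' The DE table mixes true effects (`|log2fc| = 1 + Exp(1)`, FDR ~
#' Uniform(0, 0.01)) with nulls (`log2fc ~ Normal(0, 0.3)`, FDR ~
#' Uniform(0, 1)), so true effects clear the standard thresholds and nulls
#' essentially never do.
#'
#' @param n_genes number of genes.
#' @param promoter_length promoter length (nt), default 1500.
#' @param gc_content background GC fraction in (0, 1).
#' @param planted_fraction fraction of genes with planted sites.
#' @param sites_per_planted motif copies per planted gene.
#' @param motifs IUPAC patterns to plant (default [skn1_motifs()]).
#' @param de_fraction fraction of genes that are true DE.
#' @param seed mandatory integer seed.
#' @return List with `promoters` (named character vector), `degs`
#'   (data.frame `gene_id`, `log2fc`, `fdr`) and `truth` (list:
#'   `planted_genes`, `de_genes`, `sites` data.frame with `gene_id`,
#'   `motif`, `strand`, `start` 0-based, `word`).
#' @export
generate_regulatory <- function(n_genes = 1000, promoter_length = 1500,
                                gc_content = 0.36, planted_fraction = 0.3,
                                sites_per_planted = 1,
                                motifs = skn1_motifs(),
                                de_fraction = 0.3, seed) {
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0, 1)",
                                               call. = FALSE)
  if (planted_fraction < 0 || planted_fraction > 1 ||
      de_fraction < 0 || de_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  motif_len <- nchar(motifs)
  if (promoter_length < max(motif_len)) {
    stop("promoter_length shorter than the motif", call. = FALSE)
  }
  expansions <- lapply(motifs, expand_iupac)
  with_seed(seed, {
    gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
    probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
               G = gc_content / 2, T = (1 - gc_content) / 2)
    promoters <- vapply(seq_len(n_genes), function(i) {
      paste(sample(names(probs), promoter_length, replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1))
    names(promoters) <- gene_ids

    n_planted <- round(planted_fraction * n_genes)
    planted <- sample(gene_ids, n_planted)
    sites <- NULL
    for (g in planted) {
      placed <- plant_sites(promoters[[g]], sites_per_planted, motifs,
                            expansions)
      promoters[[g]] <- placed$seq
      if (nrow(placed$sites) > 0) {
        placed$sites$gene_id <- g
        sites <- rbind(sites, placed$sites)
      }
    }
    if (is.null(sites)) {
      sites <- data.frame(gene_id = character(), motif = character(),
                          strand = character(), start = integer(),
                          word = character(), stringsAsFactors = FALSE)
    }

    n_de <- round(de_fraction * n_genes)
    de_genes <- sample(gene_ids, n_de)
    is_de <- gene_ids %in% de_genes
    log2fc <- ifelse(is_de,
                     sample(c(-1, 1), n_genes, replace = TRUE) *
                       (1 + stats::rexp(n_genes, rate = 1)),
                     stats::rnorm(n_genes, 0, 0.3))
    fdr <- ifelse(is_de, stats::runif(n_genes, 0, 0.01),
                  stats::runif(n_genes, 0, 1))
    list(
      promoters = promoters,
      degs = data.frame(gene_id = gene_ids, log2fc = log2fc, fdr = fdr,
                        stringsAsFactors = FALSE),
      truth = list(planted_genes = sort(planted), de_genes = sort(de_genes),
                   sites = sites[, c("gene_id", "motif", "strand", "start",
                                     "word")])
    )
  })
}

# insert n_sites non-overlapping concrete motif words into one promoter
plant_sites <- function(seq, n_sites, motifs, expansions) {
  L <- nchar(seq)
  occupied <- logical(L)
  out <- NULL
  for (s in seq_len(n_sites)) {
    mi <- sample.int(length(motifs), 1)
    word <- sample(expansions[[mi]], 1)
    k <- nchar(word)
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") word else revcomp_chr(word)
    free <- which(vapply(seq_len(L - k + 1),
                         function(p) !any(occupied[p:(p + k - 1)]),
                         logical(1)))
    if (length(free) == 0) {
      stop("cannot place ", n_sites, " non-overlapping sites in a ",
           L, "-nt promoter", call. = FALSE)
    }
    pos <- if (length(free) == 1) free else sample(free, 1)
    substr(seq, pos, pos + k - 1) <- ins
    occupied[pos:(pos + k - 1)] <- TRUE
    out <- rbind(out, data.frame(gene_id = NA_character_,
                                 motif = motifs[mi], strand = strand,
                                 start = pos - 1L, word = word,
                                 stringsAsFactors = FALSE))
  }
  list(seq = seq, sites = out %||% data.frame())
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
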