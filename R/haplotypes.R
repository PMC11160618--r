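# Haplotype and crossover inference.
#
# N2 offspring of an F1 sire transmit, at each marker, one of the two paternal
# grandparental alleles; expected frequencies are 0.5, so the chromosome is
# modelled as a backcross with a two-state HMM (states: grandparent A origin,
# grandparent B origin). The Viterbi path gives marker-wise haplotype states;
# uninterrupted runs are transmitted segments and crossovers are the
# boundaries between them.

#' Most probable haplotype state path along one chromosome
#'
#' Two-state Viterbi decoding in log space. Emissions: the observed call
#' matches the state's allele with probability `1 - error_rate`, mismatches
#' with `error_rate`; missing calls contribute equally to both states.
#' Transitions between adjacent markers `d` cM apart use the Haldane
#' recombination fraction `r = (1 - exp(-2 d / 100)) / 2`. The initial state
#' is uniform. Ties prefer staying in the current state, and the initial tie
#' prefers state A, so output is deterministic.
#'
#' @param calls integer calls at ordered markers: 0 = grandparent-A allele,
#'   2 = grandparent-B allele, NA = missing.
#' @param pos_cM genetic positions (cM) of the markers, non-decreasing.
#' @param error_rate genotyping error probability in `[0, 0.5)`.
#' @return List with `path` (character vector of "A"/"B"), `flagged` (`TRUE`
#'   when fewer than 2 informative (non-missing) calls are present, in which
#'   case the path defaults to the tie rule and the chromosome should be
#'   excluded from crossover data).
#' @export
viterbi_haplotypes <- function(calls, pos_cM, error_rate = 0.01) {
  stopifnot(length(calls) == length(pos_cM), length(calls) >= 1,
            error_rate >= 0, error_rate < 0.5,
            !is.unsorted(pos_cM))
  m <- length(calls)
  bad <- !is.na(calls) & !(calls %in% c(0L, 2L))
  if (any(bad)) stop("calls must be 0, 2 or NA at markers recoded to the ",
                     "paternal grandparents")
  # emission log-probabilities, rows = markers, cols = states (A, B)
  le <- matrix(log(0.5), m, 2)
  obs <- !is.na(calls)
  le[obs, 1] <- ifelse(calls[obs] == 0L, log1p(-error_rate), log(error_rate))
  le[obs, 2] <- ifelse(calls[obs] == 2L, log1p(-error_rate), log(error_rate))
  flagged <- sum(obs) < 2L

  delta <- matrix(-Inf, m, 2)
  back <- matrix(1L, m, 2)
  delta[1, ] <- log(0.5) + le[1, ]
  if (m > 1) {
    d <- diff(pos_cM)
    r <- 0.5 * (1 - exp(-2 * d / 100))
    for (i in 2:m) {
      lstay <- log1p(-r[i - 1])
      lswitch <- log(r[i - 1])
      for (s in 1:2) {
        stay <- delta[i - 1, s] + lstay
        move <- delta[i - 1, 3 - s] + lswitch
        if (move > stay) {          # strict: ties prefer staying
          delta[i, s] <- move + le[i, s]
          back[i, s] <- 3L - s
        } else {
          delta[i, s] <- stay + le[i, s]
          back[i, s] <- s
        }
      }
    }
  }
  states <- integer(m)
  states[m] <- if (delta[m, 2] > delta[m, 1]) 2L else 1L  # tie -> A
  if (m > 1) for (i in (m - 1):1) states[i] <- back[i + 1, states[i + 1]]
  list(path = c("A", "B")[states], flagged = flagged)
}

# exhaustive maximizer over all 2^m state sequences; used as a test oracle
# and by validation code, never on real-sized chromosomes
brute_force_path <- function(calls, pos_cM, error_rate = 0.01) {
  m <- length(calls)
  stopifnot(m <= 20)
  le <- matrix(log(0.5), m, 2)
  obs <- !is.na(calls)
  le[obs, 1] <- ifelse(calls[obs] == 0L, log1p(-error_rate), log(error_rate))
  le[obs, 2] <- ifelse(calls[obs] == 2L, log1p(-error_rate), log(error_rate))
  r <- 0.5 * (1 - exp(-2 * diff(pos_cM) / 100))
  best <- NULL
  best_lp <- -Inf
  for (code in 0:(2^m - 1)) {
    s <- as.integer(bitwAnd(code, 2^(seq_len(m) - 1)) > 0) + 1L
    lp <- log(0.5) + le[1, s[1]]
    if (m > 1)
      lp <- lp + sum(ifelse(s[-1] == s[-m], log1p(-r), log(r)) +
                       le[cbind(2:m, s[-1])])
    if (lp > best_lp) {
      best_lp <- lp
      best <- s
    }
  }
  list(path = c("A", "B")[best], logprob = best_lp)
}

#' Convert a haplotype state path to segments and crossovers
#'
#' Crossover positions are the midpoints (default) of the genetic positions
#' of the two markers flanking each state switch, shifted so the first marker
#' sits at 0; `L` is the genetic span of the markers. Segments are 0-based
#' half-open intervals that abut at the crossover positions and alternate
#' origin.
#'
#' @param path character vector of "A"/"B" states.
#' @param pos_cM marker genetic positions (cM).
#' @param convention within-interval placement of the crossover: `"midpoint"`
#'   (default), `"left"` or `"right"` flanking marker (the latter two are
#'   nudged inward by a negligible amount so positions stay inside `(0, L)`).
#' @return List with `L_cM`, `positions_cM`, and `segments` (data frame
#'   `start_cM`, `end_cM`, `origin`, `first_marker`, `last_marker` indices).
#' @export
segments_to_crossovers <- function(path, pos_cM,
                                   convention = c("midpoint", "left", "right")) {
  convention <- match.arg(convention)
  stopifnot(length(path) == length(pos_cM), length(path) >= 1)
  m <- length(path)
  L <- pos_cM[m] - pos_cM[1]
  sw <- which(path[-1] != path[-m])  # switch between marker sw and sw+1
  xo <- switch(convention,
               midpoint = (pos_cM[sw] + pos_cM[sw + 1]) / 2,
               left = pos_cM[sw] + 1e-9 * max(L, 1),
               right = pos_cM[sw + 1] - 1e-9 * max(L, 1))
  xo <- xo - pos_cM[1]
  bounds <- c(0, xo, L)
  runs <- c(sw, m)
  seg <- data.frame(start_cM = bounds[-length(bounds)], end_cM = bounds[-1],
                    origin = path[c(1, sw + 1)],
                    first_marker = c(1L, sw + 1L), last_marker = runs)
  list(L_cM = L, positions_cM = xo, segments = seg)
}

#' Infer haplotype segments and crossovers for a genotyped partition
#'
#' Runs [viterbi_haplotypes] and [segments_to_crossovers] for every individual
#' and chromosome of a genotype table whose markers have already passed QC.
#' Chromosomes with fewer than 2 informative markers are flagged and excluded
#' from the crossover data.
#'
#' @param genotypes data frame with `marker`, `chrom`, `cM` and one call
#'   column per individual (calls 0/2/NA relative to the paternal
#'   grandparents).
#' @param error_rate genotyping error rate assumed by the HMM.
#' @param convention crossover placement, see [segments_to_crossovers].
#' @return List with `segments` (data frame: individual, chrom, start_cM,
#'   end_cM, origin, first_marker, last_marker), `xo` (an [xo_data]) and
#'   `flagged` (data frame of excluded individual-chromosomes).
#' @export
infer_crossovers <- function(genotypes, error_rate = 0.01,
                             convention = "midpoint") {
  meta_cols <- intersect(c("marker", "chrom", "cM", "bp"), names(genotypes))
  stopifnot(all(c("marker", "chrom", "cM") %in% meta_cols))
  inds <- setdiff(names(genotypes), meta_cols)
  segs <- list()
  xo_ind <- character(0); xo_chr <- character(0)
  xo_L <- numeric(0); xo_pos <- list()
  flagged <- list()
  for (cc in unique(genotypes$chrom)) {
    gsub <- genotypes[genotypes$chrom == cc, , drop = FALSE]
    gsub <- gsub[order(gsub$cM), , drop = FALSE]
    pos <- gsub$cM
    for (id in inds) {
      calls <- gsub[[id]]
      v <- viterbi_haplotypes(calls, pos, error_rate)
      if (v$flagged) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          individual = id, chrom = cc, reason = "fewer than 2 informative markers")
        next
      }
      sc <- segments_to_crossovers(v$path, pos, convention)
      seg <- sc$segments
      seg$first_marker <- gsub$marker[seg$first_marker]
      seg$last_marker <- gsub$marker[seg$last_marker]
      segs[[length(segs) + 1L]] <- cbind(data.frame(individual = id, chrom = cc),
                                         seg)
      xo_ind <- c(xo_ind, id); xo_chr <- c(xo_chr, cc)
      xo_L <- c(xo_L, sc$L_cM); xo_pos[[length(xo_pos) + 1L]] <- sc$positions_cM
    }
  }
  list(segments = do.call(rbind, segs),
       xo = xo_data(xo_ind, xo_chr, xo_L, xo_pos),
       flagged = if (length(flagged)) do.call(rbind, flagged) else NULL)
}

#' Infer crossovers for a whole cohort after QC
#'
#' Convenience driver: for every genotype x platform partition, subsets the
#' genotype table to the QC-retained panel and that partition's individuals,
#' infers crossovers, and combines the results.
#'
#' @param cohort a `sim_cohort` (or a list with `genotypes`, `map`, `meta`).
#' @param qc a `qc_result` from [qc_pipeline].
#' @inheritParams infer_crossovers
#' @return As [infer_crossovers], combined across partitions.
#' @export
haplotype_pipeline <- function(cohort, qc, error_rate = 0.01,
                               convention = "midpoint") {
  meta <- cohort$meta
  meta$genotype <- paste(meta$maternal_strain, "x", meta$paternal_strain)
  segs <- list(); xos <- list(); flagged <- list()
  for (g in names(qc$panels)) {
    for (pl in names(qc$panels[[g]])) {
      inds <- meta$individual[meta$genotype == g & meta$platform == pl]
      if (!length(inds)) next
      panel <- qc$panels[[g]][[pl]]
      part <- cohort$genotypes[cohort$genotypes$marker %in% panel,
                               c("marker", "chrom", "cM", inds), drop = FALSE]
      r <- infer_crossovers(part, error_rate, convention)
      segs[[paste(g, pl)]] <- r$segments
      xos[[paste(g, pl)]] <- r$xo
      if (!is.null(r$flagged)) flagged[[paste(g, pl)]] <- r$flagged
    }
  }
  xo <- do.call(rbind, xos)
  class(xo) <- c("xo_data", "data.frame")
  rownames(xo) <- NULL
  list(segments = do.call(rbind, c(segs, make.row.names = FALSE)), xo = xo,
       flagged = if (length(flagged))
         do.call(rbind, c(flagged, make.row.names = FALSE)) else NULL)
}
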