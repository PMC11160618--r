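# Marker filtering and two-array harmonization.
#
# Filters are evaluated within one paternal-genotype x platform partition
# (marker informativeness depends on the paternal grandparents), in a fixed
# order: missingness -> informativeness -> segregation distortion; then, for
# genotypes typed on both arrays, density harmonization (prune the dense array
# to the nearest neighbours of sparse-array markers) and trimming of both
# panels to the common physical span.

#' Filter markers within one genotype x platform partition
#'
#' Retains autosomal markers that (1) have fewer than `max_missing` missing
#' genotypes, (2) are fixed for opposite alleles in the two founder (paternal
#' grandparent) strains, and (3) show no substantial segregation distortion:
#' the non-reference transmitted allele frequency must be strictly above
#' `freq_bounds[1]` and strictly below `freq_bounds[2]`. The reference allele
#' is the allele of the founder strain listed first in the cross label
#' (`founder_a`). Rules are applied in order and each removed marker is
#' attributed to the first rule it fails.
#'
#' @param genotypes data frame with columns `marker`, `chrom`, `cM`, `bp` and
#'   one column of calls in `{0, 1, 2, NA}` per offspring of the partition.
#' @param founders data frame with columns `marker`, `founder_a`, `founder_b`:
#'   the calls of the two paternal grandparent strains.
#' @param max_missing maximum tolerated missing fraction (exclusive bound).
#' @param freq_bounds lower and upper (exclusive) bounds on the non-reference
#'   allele frequency, `0 < low < high < 1`.
#' @return List with `markers` (retained ids, in map order) and `report`
#'   (class `filter_report`).
#' @export
filter_markers <- function(genotypes, founders, max_missing = 0.10,
                           freq_bounds = c(0.20, 0.80)) {
  stopifnot(all(c("marker", "chrom") %in% names(genotypes)),
            all(c("marker", "founder_a", "founder_b") %in% names(founders)),
            freq_bounds[1] > 0, freq_bounds[1] < freq_bounds[2],
            freq_bounds[2] < 1)
  meta_cols <- intersect(c("marker", "chrom", "cM", "bp"), names(genotypes))
  ind_cols <- setdiff(names(genotypes), meta_cols)
  if (length(ind_cols) == 0L) stop("partition contains zero individuals")
  fm <- match(genotypes$marker, founders$marker)
  if (anyNA(fm))
    stop("marker absent from founder table: ",
         paste(utils::head(genotypes$marker[is.na(fm)], 5), collapse = ", "))
  calls <- as.matrix(genotypes[, ind_cols, drop = FALSE])
  miss_frac <- rowMeans(is.na(calls))
  fa <- founders$founder_a[fm]
  fb <- founders$founder_b[fm]
  informative <- !is.na(fa) & !is.na(fb) & fa != fb
  nonref_freq <- rowMeans(calls == fb, na.rm = TRUE)

  fail_miss <- miss_frac >= max_missing
  fail_info <- !fail_miss & !informative
  fail_dist <- !fail_miss & !fail_info &
    !(nonref_freq > freq_bounds[1] & nonref_freq < freq_bounds[2])
  keep <- !(fail_miss | fail_info | fail_dist)
  report <- filter_report(
    n_input = nrow(genotypes),
    removed = c(missingness = sum(fail_miss),
                non_informative = sum(fail_info),
                distortion = sum(fail_dist)),
    retained = sum(keep))
  list(markers = genotypes$marker[keep], report = report)
}

filter_report <- function(n_input, removed, retained, span_bp = NULL) {
  stopifnot(n_input == sum(removed) + retained)
  structure(list(n_input = n_input, removed = removed, retained = retained,
                 span_bp = span_bp),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("markers in:", x$n_input, "| removed:",
      paste(names(x$removed), x$removed, sep = "=", collapse = ", "),
      "| retained:", x$retained, "\n")
  invisible(x)
}

#' Harmonize marker density between two array platforms
#'
#' For each marker on the sparse array, the nearest marker on the dense array
#' (by physical position, same chromosome) is retained; dense markers not
#' selected by any sparse marker are discarded. Markers shared between the two
#' arrays select themselves (distance zero). Ties are broken toward the more
#' proximal dense marker.
#'
#' @param dense_map,sparse_map data frames with columns `marker`, `chrom`,
#'   `bp`, sorted by chromosome then position.
#' @return List with `pairing` (data frame `sparse_marker`, `dense_marker`,
#'   `distance_bp`), `dense_markers` (the retained dense panel) and `report`.
#' @export
harmonize_arrays <- function(dense_map, sparse_map) {
  stopifnot(all(c("marker", "chrom", "bp") %in% names(dense_map)),
            all(c("marker", "chrom", "bp") %in% names(sparse_map)))
  missing_chr <- setdiff(unique(sparse_map$chrom), unique(dense_map$chrom))
  if (length(missing_chr))
    stop("chromosome on sparse array absent from dense array: ",
         paste(missing_chr, collapse = ", "))
  pairing <- do.call(rbind, lapply(seq_len(nrow(sparse_map)), function(i) {
    dsub <- dense_map[dense_map$chrom == sparse_map$chrom[i], , drop = FALSE]
    d <- abs(dsub$bp - sparse_map$bp[i])
    # which.min takes the first minimum; dsub is position-sorted, so ties
    # resolve to the more proximal dense marker
    k <- which.min(d)
    data.frame(sparse_marker = sparse_map$marker[i],
               dense_marker = dsub$marker[k], distance_bp = d[k])
  }))
  dense_markers <- dense_map$marker[dense_map$marker %in% pairing$dense_marker]
  list(pairing = pairing, dense_markers = dense_markers,
       report = filter_report(nrow(dense_map),
                              c(harmonization = nrow(dense_map) -
                                  length(dense_markers)),
                              length(dense_markers)))
}

#' Trim both platforms to their common physical span
#'
#' Per chromosome, computes `p_inner` = max of the two platforms' most
#' proximal marker positions and `d_inner` = min of the most distal positions,
#' and discards markers outside `[p_inner, d_inner]`. A chromosome left empty
#' on either platform is dropped with a warning.
#'
#' @inheritParams harmonize_arrays
#' @return List with trimmed `dense_map` and `sparse_map`, `span`
#'   (data frame `chrom`, `start_bp`, `end_bp`) and `report` (counts of
#'   span-trimmed markers across both platforms).
#' @export
trim_common_span <- function(dense_map, sparse_map) {
  chroms <- intersect(unique(dense_map$chrom), unique(sparse_map$chrom))
  keep_d <- logical(nrow(dense_map))
  keep_s <- logical(nrow(sparse_map))
  span <- list()
  for (cc in chroms) {
    di <- dense_map$chrom == cc
    si <- sparse_map$chrom == cc
    p_inner <- max(min(dense_map$bp[di]), min(sparse_map$bp[si]))
    d_inner <- min(max(dense_map$bp[di]), max(sparse_map$bp[si]))
    kd <- di & dense_map$bp >= p_inner & dense_map$bp <= d_inner
    ks <- si & sparse_map$bp >= p_inner & sparse_map$bp <= d_inner
    if (!any(kd) || !any(ks)) {
      warning("chromosome ", cc, " empty after span trimming; dropped")
      next
    }
    keep_d <- keep_d | kd
    keep_s <- keep_s | ks
    span[[cc]] <- data.frame(chrom = cc, start_bp = p_inner, end_bp = d_inner)
  }
  n_in <- nrow(dense_map) + nrow(sparse_map)
  n_out <- sum(keep_d) + sum(keep_s)
  list(dense_map = dense_map[keep_d, , drop = FALSE],
       sparse_map = sparse_map[keep_s, , drop = FALSE],
       span = do.call(rbind, span),
       report = filter_report(n_in, c(span_trim = n_in - n_out), n_out))
}

#' Run the full marker QC for every paternal genotype
#'
#' Applies [filter_markers] separately to each genotype x platform partition,
#' then, for genotypes typed on both platforms, [harmonize_arrays] and
#' [trim_common_span]. Returns the retained panel per genotype and platform
#' plus a Table-3-style summary.
#'
#' @param genotypes full genotype table (`marker`, `chrom`, `cM`, `bp`, one
#'   column per individual).
#' @param founders founder call table.
#' @param map marker map with `marker`, `chrom`, `bp`, `cM`, `platform`.
#' @param meta metadata with `individual`, `maternal_strain`,
#'   `paternal_strain`, `platform`.
#' @inheritParams filter_markers
#' @return List of class `qc_result`: `panels` (nested list
#'   genotype -> platform -> marker ids), `reports`, and `summary` data frame
#'   (genotype, platform, markers, bp covered, n individuals).
#' @export
qc_pipeline <- function(genotypes, founders, map, meta, max_missing = 0.10,
                        freq_bounds = c(0.20, 0.80)) {
  meta$genotype <- paste(meta$maternal_strain, "x", meta$paternal_strain)
  panels <- list()
  reports <- list()
  summary_rows <- list()
  for (g in sort(unique(meta$genotype))) {
    msub <- meta[meta$genotype == g, , drop = FALSE]
    platforms <- sort(unique(msub$platform))
    retained <- list()
    for (pl in platforms) {
      inds <- msub$individual[msub$platform == pl]
      mk <- map$marker[map$platform %in% c(pl, "both")]
      part <- genotypes[genotypes$marker %in% mk,
                        c("marker", "chrom", "cM", "bp", inds), drop = FALSE]
      fr <- filter_markers(part, founders, max_missing, freq_bounds)
      retained[[pl]] <- fr$markers
      reports[[paste(g, pl)]] <- fr$report
    }
    if (all(c("dense", "sparse") %in% platforms)) {
      dmap <- map[map$marker %in% retained$dense, , drop = FALSE]
      smap <- map[map$marker %in% retained$sparse, , drop = FALSE]
      h <- harmonize_arrays(dmap, smap)
      reports[[paste(g, "harmonization")]] <- h$report
      dmap <- dmap[dmap$marker %in% h$dense_markers, , drop = FALSE]
      tr <- trim_common_span(dmap, smap)
      reports[[paste(g, "span_trim")]] <- tr$report
      retained$dense <- tr$dense_map$marker
      retained$sparse <- tr$sparse_map$marker
    }
    panels[[g]] <- retained
    for (pl in platforms) {
      mk <- map[map$marker %in% retained[[pl]], , drop = FALSE]
      summary_rows[[paste(g, pl)]] <- data.frame(
        genotype = g, platform = pl, markers = nrow(mk),
        bp_covered = sum(vapply(split(mk$bp, mk$chrom),
                                function(b) diff(range(b)), numeric(1))),
        n = sum(msub$platform == pl))
    }
  }
  structure(list(panels = panels, reports = reports,
                 summary = do.call(rbind, c(summary_rows,
                                            make.row.names = FALSE))),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("marker QC summary:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
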