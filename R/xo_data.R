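#' Crossover data container
#'
#' An `xo_data` object holds one row per gamete chromosome: the genetic length
#' of the marker span (`L_cM`) and the crossover positions within it
#' (`positions_cM`, a list column of strictly increasing values in `(0, L)`).
#' This is the observation unit of the interference likelihood.
#'
#' @param individual character or factor, offspring identifier.
#' @param chrom chromosome label.
#' @param L_cM genetic length of the observed span, in centimorgans.
#' @param positions_cM list of numeric vectors (possibly empty), crossover
#'   positions in cM relative to the start of the span.
#'
#' @return A data frame of class `xo_data` with columns `individual`, `chrom`,
#'   `L_cM` and list column `positions_cM`.
#' @export
xo_data <- function(individual, chrom, L_cM, positions_cM) {
  if (!is.list(positions_cM)) positions_cM <- list(positions_cM)
  n <- length(L_cM)
  stopifnot(length(individual) == n, length(chrom) == n,
            length(positions_cM) == n)
  x <- data.frame(individual = as.character(individual),
                  chrom = as.character(chrom),
                  L_cM = as.numeric(L_cM),
                  stringsAsFactors = FALSE)
  x$positions_cM <- lapply(positions_cM, as.numeric)
  class(x) <- c("xo_data", "data.frame")
  validate_xo_data(x)
  x
}

#' @rdname xo_data
#' @param x object to validate.
#' @export
validate_xo_data <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("individual", "chrom", "L_cM", "positions_cM") %in% names(x)))
  if (any(!is.finite(x$L_cM)) || any(x$L_cM <= 0))
    stop("all chromosome lengths must be positive and finite")
  for (i in seq_len(nrow(x))) {
    p <- x$positions_cM[[i]]
    if (length(p) == 0L) next
    if (any(!is.finite(p)))
      stop("non-finite crossover position (", x$individual[i], ", ",
           x$chrom[i], ")")
    if (is.unsorted(p, strictly = TRUE))
      stop("crossover positions must be strictly increasing (",
           x$individual[i], ", ", x$chrom[i], ")")
    if (p[1] <= 0 || p[length(p)] >= x$L_cM[i])
      stop("crossover positions must lie strictly inside (0, L) (",
           x$individual[i], ", ", x$chrom[i], ")")
  }
  invisible(x)
}

#' @rdname xo_data
#' @param ... unused.
#' @export
print.xo_data <- function(x, ...) {
  nxo <- n_crossovers(x)
  cat("xo_data:", nrow(x), "gamete chromosomes from",
      length(unique(x$individual)), "individuals;",
      sum(nxo), "crossovers\n")
  invisible(x)
}

#' Crossover counts per chromosome or per individual
#'
#' @param x an `xo_data` object.
#' @param by `"chromosome"` for one count per row, `"individual"` for totals
#'   across chromosomes.
#' @return Integer vector of counts (named by individual when
#'   `by = "individual"`).
#' @export
n_crossovers <- function(x, by = c("chromosome", "individual")) {
  by <- match.arg(by)
  k <- vapply(x$positions_cM, length, integer(1))
  if (by == "chromosome") return(k)
  tapply(k, x$individual, sum)
}

#' Read and write crossover tables
#'
#' The on-disk format is a TSV with columns `individual`, `chrom`, `L_cM` and
#' `positions_cM` (comma-separated cM values, empty string for none).
#'
#' @param x an `xo_data` object.
#' @param path file path.
#' @return `read_crossovers` returns an `xo_data`; `write_crossovers` returns
#'   `path` invisibly.
#' @export
write_crossovers <- function(x, path) {
  validate_xo_data(x)
  out <- data.frame(individual = x$individual, chrom = x$chrom,
                    L_cM = x$L_cM,
                    positions_cM = vapply(x$positions_cM,
                                          function(p) paste(format(p, digits = 12, trim = TRUE),
                                                            collapse = ","),
                                          character(1)))
  out$positions_cM[vapply(x$positions_cM, length, integer(1)) == 0L] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crossovers
#' @export
read_crossovers <- function(path) {
  d <- utils::read.delim(path, colClasses = c("character", "character",
                                              "numeric", "character"))
  pos <- lapply(d$positions_cM, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  })
  xo_data(d$individual, d$chrom, d$L_cM, pos)
}

#' Subset crossover data to a set of individuals, keeping duplicates distinct
#'
#' Used by the bootstrap: individuals drawn with replacement are relabelled
#' `id.1`, `id.2`, ... so repeated draws contribute independent copies.
#'
#' @param x an `xo_data` object.
#' @param individuals character vector of individual ids, possibly repeated.
#' @return An `xo_data` for the resampled individuals.
#' @keywords internal
resample_individuals <- function(x, individuals) {
  idx <- split(seq_len(nrow(x)), x$individual)
  rows <- integer(0)
  labs <- character(0)
  for (j in seq_along(individuals)) {
    r <- idx[[individuals[j]]]
    if (is.null(r)) stop("unknown individual: ", individuals[j])
    rows <- c(rows, r)
    labs <- c(labs, rep(paste0(individuals[j], ".", j), length(r)))
  }
  out <- x[rows, , drop = FALSE]
  out$individual <- labs
  rownames(out) <- NULL
  class(out) <- c("xo_data", "data.frame")
  out
}
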