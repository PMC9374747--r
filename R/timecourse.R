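#' Replicate-level omic time course for one layer
#'
#' Container for abundances of one omic layer (metabolite, gene counts or
#' phosphorylation) measured in two genotypes (WT, OB) over a shared grid of
#' sampling times that must start at the 0-min fasting baseline. Values are
#' stored as a 4-d array molecule x genotype x time x replicate; missing
#' cells are NA (never zero).
#'
#' @param values numeric 4-d array with dims (molecule, genotype, time,
#'   replicate). dimnames must give molecule ids, genotypes ("WT","OB") and
#'   times in minutes (as character); replicate dimnames are optional.
#' @param layer one of "metabolite", "gene", "phospho".
#' @param replicate_counts optional genotype x time integer matrix of
#'   declared replicate counts; defaults to the replicate dimension size.
#' @return an object of class \code{omics_timecourse}.
#' @export
omics_timecourse <- function(values, layer = c("metabolite", "gene", "phospho"),
                             replicate_counts = NULL) {
  layer <- match.arg(layer)
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("'values' must be a 4-d array (molecule x genotype x time x replicate)")
  dn <- dimnames(values)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]) || is.null(dn[[3]]))
    stop("'values' needs dimnames for molecules, genotypes and times")
  genotypes <- dn[[2]]
  if (!setequal(genotypes, c("WT", "OB")))
    stop("genotypes must be exactly WT and OB")
  times <- suppressWarnings(as.numeric(dn[[3]]))
  if (anyNA(times)) stop("time dimnames must be numeric minutes")
  if (any(diff(times) <= 0)) stop("time points must be strictly increasing")
  if (times[1] != 0) stop("time points must include the 0-min fasting baseline")
  if (any(times < 0)) stop("time points must be non-negative")
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop("negative abundance for molecule '", dn[[1]][neg[1, 1]], "'")
  if (is.null(replicate_counts)) {
    replicate_counts <- matrix(dim(values)[4], nrow = 2, ncol = length(times),
                               dimnames = list(genotypes, dn[[3]]))
  }
  structure(list(values = values, layer = layer, times = times,
                 replicate_counts = replicate_counts),
            class = "omics_timecourse")
}

#' @export
print.omics_timecourse <- function(x, ...) {
  cat(sprintf("<omics_timecourse> layer=%s  %d molecules, %d time points, up to %d replicates\n",
              x$layer, length(tc_molecules(x)), length(x$times), dim(x$values)[4]))
  invisible(x)
}

#' Molecule identifiers of a time course
#' @param tc an \code{omics_timecourse}.
#' @return character vector of molecule ids.
#' @export
tc_molecules <- function(tc) dimnames(tc$values)[[1]]

#' Sampling times (minutes) of a time course
#' @param tc an \code{omics_timecourse}.
#' @return numeric vector of minutes, starting at 0.
#' @export
tc_times <- function(tc) tc$times

#' Replicate-averaged traces
#'
#' Arithmetic means over non-missing replicates on the raw scale, per
#' molecule x genotype x time.
#' @param tc an \code{omics_timecourse}.
#' @return 3-d array (molecule x genotype x time); NaN where no replicate
#'   was observed.
#' @export
tc_mean_traces <- function(tc) {
  apply(tc$values, c(1, 2, 3), function(v) mean(v, na.rm = TRUE))
}

# replicate matrix (molecules x replicates) for one genotype/time
tc_slice <- function(tc, genotype, time) {
  m <- tc$values[, genotype, as.character(time), , drop = FALSE]
  dim(m) <- c(dim(tc$values)[1], dim(tc$values)[4])
  rownames(m) <- tc_molecules(tc)
  m
}

parse_value_column <- function(nm) {
  parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
  if (length(parts) != 3L || !parts[1] %in% c("WT", "OB") ||
      is.na(suppressWarnings(as.numeric(parts[2]))) ||
      is.na(suppressWarnings(as.integer(parts[3]))))
    stop("malformed value-column header '", nm,
         "' (expected <genotype>_<time>_<replicate>, e.g. WT_0_1)")
  list(genotype = parts[1], time = as.numeric(parts[2]),
       replicate = as.integer(parts[3]))
}

#' Read an omic time-course table
#'
#' Tab-separated, UTF-8, "." decimal, empty cell = missing. First column is
#' \code{molecule_id}; every further column is named
#' \code{<genotype>_<time>_<replicate>} (e.g. \code{WT_0_1}) declaring the
#' genotype, sampling minute and replicate index of its values.
#'
#' @param path TSV file path.
#' @param layer omic layer of the table.
#' @return a validated \code{omics_timecourse}; missing cells stay NA.
#' @export
read_timecourse_table <- function(path, layer = c("metabolite", "gene", "phospho")) {
  layer <- match.arg(layer)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "molecule_id")
    stop("first column must be 'molecule_id'")
  ids <- as.character(df[[1]])
  meta <- lapply(names(df)[-1], parse_value_column)
  genos <- vapply(meta, `[[`, "", "genotype")
  times <- vapply(meta, `[[`, 0, "time")
  reps  <- vapply(meta, `[[`, 0L, "replicate")
  utimes <- sort(unique(times))
  if (!0 %in% utimes)
    stop("validation error: no 0-min (fasting baseline) column present")
  vals <- array(NA_real_,
                dim = c(length(ids), 2L, length(utimes), max(reps)),
                dimnames = list(ids, c("WT", "OB"), as.character(utimes), NULL))
  for (j in seq_along(meta)) {
    col <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(!is.na(col) & col < 0)
    if (length(bad))
      stop("validation error: negative abundance in row '", ids[bad[1]],
           "', column '", names(df)[j + 1L], "'")
    vals[, genos[j], as.character(times[j]), reps[j]] <- col
  }
  rc <- matrix(0L, 2L, length(utimes), dimnames = list(c("WT", "OB"), as.character(utimes)))
  for (g in c("WT", "OB")) for (t in as.character(utimes))
    rc[g, t] <- sum(genos == g & times == as.numeric(t))
  omics_timecourse(vals, layer, replicate_counts = rc)
}

#' Write an omic time-course table
#'
#' Inverse of \code{\link{read_timecourse_table}}: one molecule per row,
#' value columns named \code{<genotype>_<time>_<replicate>}, NA written as
#' empty cells.
#' @param tc an \code{omics_timecourse}.
#' @param path output TSV path.
#' @export
write_timecourse_table <- function(tc, path) {
  ids <- tc_molecules(tc)
  out <- list(molecule_id = ids)
  for (g in c("WT", "OB")) for (t in as.character(tc$times)) {
    nrep <- tc$replicate_counts[g, t]
    for (r in seq_len(nrep)) {
      out[[paste(g, t, r, sep = "_")]] <- tc$values[, g, t, r]
    }
  }
  df <- as.data.frame(out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Remove molecules with insufficient replicate detection
#'
#' A molecule is removed if, for some genotype and some post-administration
#' time point (t > 0), the fraction of non-missing replicates falls strictly
#' below \code{min_fraction} of the declared replicate count ("detected in
#' less than half of the replicates" at the default 0.5).
#'
#' @param tc an \code{omics_timecourse}.
#' @param min_fraction minimum retained fraction (default 0.5).
#' @return the filtered \code{omics_timecourse} (possibly with 0 molecules).
#' @export
filter_detected <- function(tc, min_fraction = 0.5) {
  post <- as.character(tc$times[tc$times > 0])
  keep <- rep(TRUE, length(tc_molecules(tc)))
  for (g in c("WT", "OB")) for (t in post) {
    nrep <- tc$replicate_counts[g, t]
    nobs <- apply(tc$values[, g, t, , drop = FALSE], 1, function(v) sum(!is.na(v)))
    keep <- keep & (nobs / nrep >= min_fraction)
  }
  message(sprintf("filter_detected [%s]: %d of %d molecules retained",
                  tc$layer, sum(keep), length(keep)))
  sub <- tc$values[keep, , , , drop = FALSE]
  omics_timecourse(sub, tc$layer, replicate_counts = tc$replicate_counts)
}

#' Scale count replicates to a common library size
#'
#' For count layers, each replicate sample (genotype x time x replicate) is
#' scaled so that its total over molecules equals the median total across
#' all samples. Samples with zero total are left unscaled.
#' @param tc an \code{omics_timecourse} (gene layer).
#' @return the scaled \code{omics_timecourse}.
#' @export
scale_library_sizes <- function(tc) {
  v <- tc$values
  totals <- apply(v, c(2, 3, 4), function(x) sum(x, na.rm = TRUE))
  target <- stats::median(totals[totals > 0])
  for (g in seq_len(dim(v)[2])) for (t in seq_len(dim(v)[3]))
    for (r in seq_len(dim(v)[4])) {
      tot <- totals[g, t, r]
      if (tot > 0) v[, g, t, r] <- v[, g, t, r] * (target / tot)
    }
  out <- tc
  out$values <- v
  out
}
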