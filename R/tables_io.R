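#' Construct a validated abundance table
#'
#' An abundance table holds non-negative relative abundances of features
#' (gene families or taxa) across samples.  Values are either fractions of
#' the annotated genes/sequences per sample (unit `"fraction"`, column sums
#' at most 1) or percentages (unit `"percent"`).
#'
#' @param values numeric matrix, features in rows and samples in columns;
#'   rownames are feature ids, colnames are sample ids.
#' @param feature_kinds character vector of per-feature kinds, each
#'   `"gene_family"` or `"taxon"`; a single value is recycled.
#' @param unit `"fraction"` or `"percent"`.
#' @return An object of class `abund_table`: a list with elements `values`,
#'   `feature_kinds` and `unit`.
#' @examples
#' m <- matrix(c(0.2, 0.3, 0.5, 0.1, 0.4, 0.5), nrow = 3,
#'             dimnames = list(c("GH13", "CE1", "CBM48"), c("S1", "S2")))
#' abundance_table(m, feature_kinds = "gene_family")
#' @export
abundance_table <- function(values, feature_kinds = "gene_family",
                            unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature ids as rownames and sample ids as colnames")
  fid <- rownames(values)
  sid <- colnames(values)
  if (anyDuplicated(fid))
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("abundance values must be finite and numeric")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 fid[bad[1L]], sid[bad[2L]]))
  }
  if (length(feature_kinds) == 1L)
    feature_kinds <- rep(feature_kinds, nrow(values))
  if (length(feature_kinds) != nrow(values))
    stop("`feature_kinds` must have one entry per feature")
  if (!all(feature_kinds %in% c("gene_family", "taxon")))
    stop("feature kinds must be 'gene_family' or 'taxon'")
  if (unit == "fraction" && any(colSums(values) > 1 + 1e-9)) {
    bad <- sid[colSums(values) > 1 + 1e-9]
    stop("column sums exceed 1 for unit 'fraction': ",
         paste(bad, collapse = ", "))
  }
  structure(list(values = values, feature_kinds = feature_kinds, unit = unit),
            class = "abund_table")
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d features (%d gene_family, %d taxon) x %d samples [%s]\n",
              nrow(x$values), sum(x$feature_kinds == "gene_family"),
              sum(x$feature_kinds == "taxon"), ncol(x$values), x$unit))
  invisible(x)
}

#' Feature and sample identifiers of an abundance table
#' @param x an `abund_table`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an abundance table from TSV
#'
#' Expects a UTF-8 tab-separated file with a header row of sample ids whose
#' first cell is `feature_id`, one row per feature, `.` decimal separator and
#' no quoting.  Percent tables are converted to fractions once at load, so
#' every in-memory table carries unit `"fraction"`.
#'
#' @param path file path.
#' @param unit unit of the values on disk, `"fraction"` or `"percent"`.
#' @param feature_kind kind label applied to all features in the file
#'   (`"gene_family"` or `"taxon"`), or a vector with one entry per row.
#' @return An [abundance_table()] with unit `"fraction"`, preserving the
#'   input row and column order.
#' @export
read_abundance_table <- function(path, unit = c("fraction", "percent"),
                                 feature_kind = "gene_family") {
  unit <- match.arg(unit)
  raw <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "", dec = ".",
                      comment.char = ""),
    error = function(e) stop("no features: cannot read table from ", path))
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("no features: ", path, " has no data rows")
  fid <- as.character(raw[[1L]])
  if (anyDuplicated(fid))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(conv <- as.numeric(vals[[j]]))
      bad <- which(is.na(conv) & !is.na(vals[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                     fid[bad[1L]], colnames(vals)[j]))
      vals[[j]] <- conv
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- fid
  if (unit == "percent") m <- m / 100
  abundance_table(m, feature_kinds = feature_kind, unit = "fraction")
}

#' Write an abundance table as TSV
#'
#' Emits the same dialect [read_abundance_table()] consumes (header cell
#' `feature_id`, tabs, `.` decimals, no quoting), so read -> write -> read
#' round-trips bit-identically.
#'
#' @param x an `abund_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abund_table"))
  header <- paste(c("feature_id", colnames(x$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(x$values)), function(i)
    paste(c(rownames(x$values)[i], as.character(x$values[i, ])),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' TSV with columns `sample_id`, `do_class` (aerobic/anaerobic),
#' `temperature_class` (A/M/T for ambient, mesophilic, thermophilic) and
#' `salinity_class` (fresh/saline).
#'
#' @param path file path.
#' @return A data frame with validated factor columns.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  validate_sample_metadata(md)
}

#' Validate a sample-metadata data frame
#' @param md data frame with columns `sample_id`, `do_class`,
#'   `temperature_class`, `salinity_class`.
#' @return `md`, with checked columns.
#' @export
validate_sample_metadata <- function(md) {
  need <- c("sample_id", "do_class", "temperature_class", "salinity_class")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  chk <- function(col, levels) {
    bad <- setdiff(unique(md[[col]]), levels)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                   paste(bad, collapse = ", "), paste(levels, collapse = ", ")))
  }
  chk("do_class", c("aerobic", "anaerobic"))
  chk("temperature_class", c("A", "M", "T"))
  chk("salinity_class", c("fresh", "saline"))
  md
}

#' Write a sample-metadata table as TSV
#' @param md metadata data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize feature counts to relative abundances
#'
#' Divides each count by the per-sample total of annotated genes/sequences.
#'
#' @param counts non-negative feature x sample count matrix with dimnames.
#' @param totals per-sample totals of annotated genes, strictly positive,
#'   in column order.
#' @param feature_kinds passed to [abundance_table()].
#' @return An [abundance_table()] with unit `"fraction"`.
#' @examples
#' cts <- matrix(c(2, 3, 5), 3, dimnames = list(c("a", "b", "c"), "S1"))
#' normalize_counts(cts, 10)$values
#' @export
normalize_counts <- function(counts, totals, feature_kinds = "gene_family") {
  counts <- as.matrix(counts)
  if (length(totals) != ncol(counts))
    stop("`totals` must have one entry per sample column")
  if (any(totals <= 0))
    stop("per-sample totals must be strictly positive")
  if (any(counts < 0))
    stop("counts must be non-negative")
  over <- counts > rep(totals, each = nrow(counts))
  if (any(over)) {
    bad <- which(over, arr.ind = TRUE)[1L, ]
    stop(sprintf("count exceeds the sample total at feature '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  vals <- sweep(counts, 2L, totals, `/`)
  abundance_table(vals, feature_kinds = feature_kinds, unit = "fraction")
}

#' Concordance between two replicate profiles
#'
#' Ordinary least-squares regression (with intercept) of replicate `b` on
#' replicate `a`, used to judge sequencing reproducibility: good replicates
#' show a slope near 1 and R-squared near 1.
#'
#' @param a,b numeric abundance vectors over identical features; if named,
#'   they are aligned on the shared names.
#' @return A list of class `replicate_concordance` with `slope`,
#'   `r_squared` and `n_features`.
#' @export
replicate_concordance <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]
    b <- b[shared]
  } else if (length(a) != length(b)) {
    stop("unnamed replicate vectors must have equal length")
  }
  if (length(a) < 3L)
    stop("fewer than 3 shared features between replicates")
  fit <- stats::lm(b ~ a)
  sstot <- sum((b - mean(b))^2)
  ssres <- sum(stats::residuals(fit)^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 r_squared = if (sstot > 0) 1 - ssres / sstot else NA_real_,
                 n_features = length(a)),
            class = "replicate_concordance")
}

#' @export
print.replicate_concordance <- function(x, ...) {
  cat(sprintf("Replicate concordance over %d features: slope %.3f, R^2 %.3f\n",
              x$n_features, x$slope, x$r_squared))
  invisible(x)
}

#' Average two biological replicates element-wise
#'
#' Biological replicates of the same source are averaged before
#' between-sample comparison; the result carries the source label.
#'
#' @param a,b `abund_table`s over identical feature sets with the same
#'   number of samples (matched positionally).
#' @param label sample id(s) for the averaged column(s); defaults to `a`'s.
#' @return An [abundance_table()] of element-wise means.
#' @export
average_biological_replicates <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "abund_table"), inherits(b, "abund_table"))
  fa <- feature_ids(a)
  fb <- feature_ids(b)
  if (!setequal(fa, fb) || length(fa) != length(fb)) {
    only_a <- setdiff(fa, fb)
    only_b <- setdiff(fb, fa)
    stop("replicate tables differ in features; only in first: [",
         paste(only_a, collapse = ", "), "], only in second: [",
         paste(only_b, collapse = ", "), "]")
  }
  if (ncol(a$values) != ncol(b$values))
    stop("replicate tables must have the same number of samples")
  if (a$unit != b$unit)
    stop("replicate tables must share a unit")
  vb <- b$values[fa, , drop = FALSE]
  vals <- (a$values + vb) / 2
  if (is.null(label)) label <- colnames(a$values)
  if (length(label) != ncol(vals))
    stop("`label` must supply one id per averaged sample")
  colnames(vals) <- label
  abundance_table(vals, feature_kinds = a$feature_kinds, unit = a$unit)
}

#' Split an abundance table by feature kind
#'
#' Inverse of [combine_features()]: returns the gene-family and taxon
#' sub-tables of a mixed table.
#'
#' @param x an `abund_table`.
#' @return A list with elements `gene_family` and `taxon` (an element is
#'   `NULL` when the table has no feature of that kind).
#' @export
split_by_kind <- function(x) {
  stopifnot(inherits(x, "abund_table"))
  out <- lapply(c(gene_family = "gene_family", taxon = "taxon"), function(k) {
    i <- which(x$feature_kinds == k)
    if (!length(i)) return(NULL)
    abundance_table(x$values[i, , drop = FALSE],
                    feature_kinds = x$feature_kinds[i], unit = x$unit)
  })
  out
}

#' Stack two abundance tables over the same samples
#'
#' Used to combine the gene-family and taxon tables before all-pairs
#' correlation, so family-family, taxon-taxon and family-taxon pairs are
#' all tested.
#'
#' @param a,b `abund_table`s with identical sample ids and disjoint
#'   feature ids.
#' @return An [abundance_table()]. Column sums may exceed 1, so the unit
#'   check is applied per source table, not to the stack; the result keeps
#'   unit `"fraction"` semantics per feature.
#' @export
combine_features <- function(a, b) {
  stopifnot(inherits(a, "abund_table"), inherits(b, "abund_table"))
  if (!identical(sample_ids(a), sample_ids(b))) {
    if (!setequal(sample_ids(a), sample_ids(b)))
      stop("tables do not share the same sample set")
    b$values <- b$values[, sample_ids(a), drop = FALSE]
  }
  if (length(intersect(feature_ids(a), feature_ids(b))))
    stop("feature ids overlap between the two tables")
  vals <- rbind(a$values, b$values)
  out <- structure(list(values = vals,
                        feature_kinds = c(a$feature_kinds, b$feature_kinds),
                        unit = a$unit),
                   class = "abund_table")
  out
}
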