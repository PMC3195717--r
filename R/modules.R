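#' Partition residues into dynamical modules by response time
#'
#' Residues responding within the same fixed time interval belong to the
#' same dynamical module: module id = floor(dt / width) + 1 with
#' half-open bins [(k-1) w, k w), so perturbed residues (dt = 0) fall in
#' module 1 and a response time exactly at a bin edge goes to the higher
#' module.  The default width of 100 fs (0.1 ps) yields seven modules for
#' a process that completes within ~0.7 ps.
#'
#' @param profile a `response_profile`.
#' @param width bin width in fs (> 0), default 100.
#' @return a `module_partition`: integer module id per residue (NA for
#'   nonresponsive) with attributes `width` and `nonresponsive`.
#' @export
partition_modules <- function(profile, width = 100) {
  ed_assert(width > 0, "enerdiss_input_error", "width must be > 0")
  dt <- as.numeric(profile)
  id <- ifelse(is.na(dt), NA_integer_, as.integer(floor(dt / width) + 1))
  structure(id, width = width,
            nonresponsive = which(is.na(dt)),
            class = "module_partition")
}

#' Cross-tabulate dynamical modules against structural regions
#'
#' @param partition a `module_partition`.
#' @param annotation a `region_annotation` of the same residues.
#' @param n_modules optional number of module columns; defaults to the
#'   largest occupied module id.  Empty modules are kept as zero columns
#'   so tables from different runs are comparable.
#' @return a `module_region_table`: integer counts matrix (regions x
#'   modules) with attributes `row_margin`, `col_margin`, `total`.
#' @export
module_region_table <- function(partition, annotation,
                                n_modules = NULL) {
  ed_assert(length(partition) == length(annotation),
            "enerdiss_input_error",
            "annotation does not cover the partition's residues")
  resp <- !is.na(partition)
  if (is.null(n_modules)) n_modules <- max(partition[resp], 1L)
  regions <- unique(c(attr(annotation, "labels"),
                      as.character(unique(annotation))))
  counts <- table(
    factor(as.character(annotation)[resp], levels = regions),
    factor(partition[resp], levels = seq_len(n_modules)))
  counts <- matrix(as.integer(counts), nrow = length(regions),
                   dimnames = list(region = regions,
                                   module = seq_len(n_modules)))
  # conservation: every responsive residue lands in exactly one cell
  stopifnot(sum(counts) == sum(resp))
  structure(counts,
            row_margin = rowSums(counts),
            col_margin = colSums(counts),
            total = sum(counts),
            class = c("module_region_table", "matrix"))
}

#' @export
print.module_region_table <- function(x, ...) {
  m <- cbind(unclass(x), Total = attr(x, "row_margin"))
  m <- rbind(m, Total = c(attr(x, "col_margin"), attr(x, "total")))
  print(m)
  invisible(x)
}

#' Variant-minus-wild-type dissipation difference curve
#'
#' dNR(t) = NR_variant(t) - NR_wildtype(t).  A positive peak means the
#' variant's residues respond earlier than the wild-type's.  Curves on
#' different grids are aligned by step-function (last-observation)
#' interpolation onto their common time span.
#'
#' @param curve_wt,curve_var `dissipation_curve`s.
#' @return data.frame (t, dNR) of class `difference_curve`.
#' @export
variant_difference <- function(curve_wt, curve_var) {
  if (isTRUE(all.equal(curve_wt$t, curve_var$t, tolerance = 0))) {
    t <- curve_wt$t
    dnr <- curve_var$NR - curve_wt$NR
  } else {
    lo <- max(min(curve_wt$t), min(curve_var$t))
    hi <- min(max(curve_wt$t), max(curve_var$t))
    ed_assert(lo < hi, "enerdiss_alignment_error",
              "curves have disjoint time grids")
    t <- sort(unique(c(curve_wt$t[curve_wt$t >= lo & curve_wt$t <= hi],
                       curve_var$t[curve_var$t >= lo & curve_var$t <= hi])))
    step <- function(cv) stats::approx(cv$t, cv$NR, xout = t,
                                       method = "constant", f = 0,
                                       rule = 2)$y
    dnr <- step(curve_var) - step(curve_wt)
  }
  structure(data.frame(t = t, dNR = dnr),
            class = c("difference_curve", "data.frame"))
}

#' Difference of two module-region tables
#'
#' Elementwise variant-minus-reference count differences, padded to the
#' common module range, for the same regions.
#'
#' @param p1,p2 `module_partition`s with identical bin width (p2 - p1).
#' @param annotation shared `region_annotation`.
#' @return integer matrix of count differences (regions x modules).
#' @export
compare_partitions <- function(p1, p2, annotation) {
  ed_assert(isTRUE(all.equal(attr(p1, "width"), attr(p2, "width"))),
            "enerdiss_spec_error", "partitions have different bin widths")
  nm <- max(max(p1, 1L, na.rm = TRUE), max(p2, 1L, na.rm = TRUE))
  t1 <- module_region_table(p1, annotation, n_modules = nm)
  t2 <- module_region_table(p2, annotation, n_modules = nm)
  unclass(t2) - unclass(t1)
}
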