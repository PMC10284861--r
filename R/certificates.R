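#' Property value functions
#'
#' Certificates rank nonnegative scalar "property values" of an inference
#' against values observed during calibration.  Small values are good by
#' convention; each function here quantifies one model design element.
#'
#' * `property_sparsity`: number of entries with magnitude above `zero_tol`
#'   (an l0 count with a numerical tolerance — iterative solvers produce
#'   near-zeros, not exact zeros).  The default tolerance is scale-invariant:
#'   `1e-6 * max(1, max|x|)`.
#' * `property_rel_error`: relative measurement error `||Ax - d|| / ||d||`.
#' * `property_total_variation`: anisotropic total variation of an image,
#'   the l1 norm of forward differences along both axes (no wraparound).
#' * `property_box_distance`: Euclidean distance from `x` to the box
#'   `[lo, hi]^n`.
#' * `property_iterate_residual`: the final iterate residual
#'   `||x_k - x_{k-1}||` of a solver run (convergence quality).
#' * [learned_prox_residual()]: distance of `x` from the fixed points of a
#'   learned proximal (data-driven regularization quality).
#'
#' @param x numeric vector (or matrix for `property_total_variation`).
#' @param zero_tol nonnegative magnitude threshold for the l0 count.
#' @return a single nonnegative number.
#' @name property_values
NULL

#' @rdname property_values
#' @export
property_sparsity <- function(x, zero_tol = NULL) {
  if (is.null(zero_tol)) zero_tol <- 1e-6 * max(1, max(abs(x)))
  check_scalar(zero_tol, "zero_tol", lower = 0)
  sum(abs(x) > zero_tol)
}

#' @rdname property_values
#' @param A measurement [linear_map()] or matrix.
#' @param d measurement vector; must be nonzero (the relative error is
#'   undefined at `d = 0`).
#' @export
property_rel_error <- function(A, x, d) {
  if (!inherits(A, "linear_map")) A <- make_matrix_map(A)
  nd <- l2norm(d)
  if (nd == 0) stop("relative error undefined for d = 0", call. = FALSE)
  l2norm(map_forward(A, x) - d) / nd
}

#' @rdname property_values
#' @param image numeric matrix (at least 1 x 1).
#' @export
property_total_variation <- function(image) {
  image <- as.matrix(image)
  tv <- 0
  if (nrow(image) > 1) tv <- tv + sum(abs(diff(image)))
  if (ncol(image) > 1) tv <- tv + sum(abs(t(diff(t(image)))))
  tv
}

#' @rdname property_values
#' @param lo,hi box bounds.
#' @export
property_box_distance <- function(x, lo = 0, hi = 1) {
  l2norm(x - project_box(x, lo, hi))
}

#' @rdname property_values
#' @param state a `fixed_point_state` with at least one completed iteration.
#' @export
property_iterate_residual <- function(state) {
  stopifnot(inherits(state, "fixed_point_state"))
  if (state$k < 1L) stop("no iterations recorded", call. = FALSE)
  state$residual
}

# ---------------------------------------------------------------------------
# Property specs, calibration, CDF, labels
# ---------------------------------------------------------------------------

#' Declare a named certificate property
#'
#' @param name identifier for the property.
#' @param evaluate function mapping an inference record (any list your
#'   pipeline produces) to a finite nonnegative scalar.
#' @param description one-line human description.
#' @return object of class `property_spec`.
#' @export
property_spec <- function(name, evaluate, description = "") {
  stopifnot(is.character(name), length(name) == 1L, is.function(evaluate))
  structure(list(name = name, evaluate = evaluate, description = description),
            class = "property_spec")
}

#' Calibrate a property on a set of records
#'
#' Evaluates the property on every record and stores the sorted sample of
#' values; these samples define the empirical CDF used to label future
#' inferences.  Calibration is deterministic: recalibrating on the same
#' records gives an identical table.
#'
#' @param property a [property_spec()].
#' @param records nonempty list of inference records (or of ground-truth
#'   records — the `source` field records which).
#' @param source provenance tag, conventionally `"training-inferences"` or
#'   `"ground-truths"`.
#' @return object of class `calibration_table` with fields `name`, `samples`
#'   (sorted ascending), `N`, `source`.
#' @export
calibrate <- function(property, records, source = "training-inferences") {
  stopifnot(inherits(property, "property_spec"))
  if (length(records) == 0L) stop("`records` must be nonempty", call. = FALSE)
  vals <- vapply(records, function(r) {
    v <- property$evaluate(r)
    if (!is.finite(v) || v < 0)
      stop(sprintf("property '%s' produced a non-finite or negative value", property$name),
           call. = FALSE)
    v
  }, numeric(1))
  structure(list(name = property$name, samples = sort(vals),
                 N = length(vals), source = source),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table '%s': N=%d from %s, range [%.4g, %.4g]>\n",
              x$name, x$N, x$source, x$samples[1], x$samples[x$N]))
  invisible(x)
}

#' Empirical CDF of a calibration table
#'
#' `CDF(alpha) = #\{alpha_i <= alpha\} / N` — the right-continuous empirical
#' distribution function of the stored samples, evaluated by binary search
#' (ties counted inclusively).  `ties = "strict"` instead counts samples
#' strictly below `alpha` (the left-continuous CDF); the two differ only at
#' atoms, and certificate labelling uses the strict form so that an inference
#' exactly tied with calibration mass — e.g. a constraint distance of exactly
#' zero, shared by every calibrated inference of a constraint-satisfying
#' model — ranks with, not above, that mass.
#'
#' @param alpha nonnegative query value.
#' @param table a [calibrate()]d table.
#' @param ties `"inclusive"` (default) or `"strict"`.
#' @return a number in `[0, 1]`.
#' @export
empirical_cdf <- function(alpha, table, ties = c("inclusive", "strict")) {
  stopifnot(inherits(table, "calibration_table"))
  ties <- match.arg(ties)
  # findInterval is a binary search over the sorted samples
  if (ties == "inclusive") {
    findInterval(alpha, table$samples) / table$N
  } else {
    findInterval(alpha, table$samples, left.open = TRUE) / table$N
  }
}

#' Label policy: probabilities of pass, warning, fail
#'
#' @param p_pass,p_warn,p_fail probabilities in `[0, 1]` summing to exactly 1.
#' @return object of class `label_policy`.
#' @export
label_policy <- function(p_pass = 0.95, p_warn = 0, p_fail = 1 - p_pass - p_warn) {
  for (p in list(p_pass, p_warn, p_fail))
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
      stop("label probabilities must lie in [0, 1]", call. = FALSE)
  if (p_pass + p_warn + p_fail != 1)
    stop("label probabilities must sum to 1 exactly", call. = FALSE)
  structure(list(p_pass = p_pass, p_warn = p_warn, p_fail = p_fail),
            class = "label_policy")
}

#' Map a CDF value to a certificate label
#'
#' `pass` when `cdf < p_pass`, `warning` when `cdf` lies in
#' `[p_pass, 1 - p_fail)`, `fail` otherwise — half-open bands, so every CDF
#' value receives exactly one label.
#'
#' @param cdf number in `[0, 1]`.
#' @param policy a [label_policy()].
#' @return one of `"pass"`, `"warning"`, `"fail"`.
#' @export
assign_label <- function(cdf, policy = label_policy()) {
  stopifnot(inherits(policy, "label_policy"))
  if (!is.numeric(cdf) || length(cdf) != 1L || is.na(cdf) || cdf < 0 || cdf > 1)
    stop("`cdf` must be a number in [0, 1]", call. = FALSE)
  if (cdf < policy$p_pass) "pass"
  else if (cdf < 1 - policy$p_fail) "warning"
  else "fail"
}

#' Certify an inference record
#'
#' Evaluates each property on the record, ranks the value with the strict
#' (left-continuous) empirical CDF of its calibration table, and labels it via
#' the policy.  The record is trustworthy exactly when every certificate is a
#' pass.
#'
#' @param record inference record understood by the property `evaluate`
#'   functions.
#' @param properties list of [property_spec()]s.
#' @param tables named list of [calibrate()]d tables; every property name must
#'   be present.
#' @param policy a [label_policy()].
#' @return a `data.frame` of class `certificates` with columns `name`, `label`,
#'   `value`, `cdf`, in property order, plus attribute `trustworthy`.
#' @export
certify <- function(record, properties, tables, policy = label_policy()) {
  if (length(properties) == 0L) {
    out <- data.frame(name = character(0), label = character(0),
                      value = numeric(0), cdf = numeric(0))
    class(out) <- c("certificates", "data.frame")
    attr(out, "trustworthy") <- TRUE
    return(out)
  }
  rows <- lapply(properties, function(p) {
    stopifnot(inherits(p, "property_spec"))
    tab <- tables[[p$name]]
    if (is.null(tab))
      stop(sprintf("no calibration table for property '%s'", p$name), call. = FALSE)
    val <- p$evaluate(record)
    cdf <- empirical_cdf(val, tab, ties = "strict")
    data.frame(name = p$name, label = assign_label(cdf, policy),
               value = val, cdf = cdf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("certificates", "data.frame")
  attr(out, "trustworthy") <- all(out$label == "pass")
  out
}

#' @export
print.certificates <- function(x, ...) {
  marks <- c(pass = "[ok]", warning = "[!]", fail = "[FAIL]")
  cat("certificates:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-24s %-7s value %.6g  cdf %.3f\n",
                x$name[i], marks[[x$label[i]]], x$value[i], x$cdf[i]))
  cat(if (isTRUE(attr(x, "trustworthy"))) "  => trustworthy\n"
      else "  => NOT trustworthy\n")
  invisible(x)
}

#' Is an inference trustworthy?
#'
#' @param certs a `certificates` frame from [certify()].
#' @return `TRUE` iff all labels are `pass`.
#' @export
is_trustworthy <- function(certs) {
  isTRUE(all(certs$label == "pass"))
}

#' Serialize certificates to JSON
#'
#' @param certs a `certificates` frame.
#' @param policy the [label_policy()] used.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_certificates <- function(certs, policy, path) {
  payload <- list(
    certificates = certs[, c("name", "label", "value", "cdf")],
    policy = unclass(policy),
    trustworthy = is_trustworthy(certs))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
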