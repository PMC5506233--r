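#' Summarized genetic association dataset for Mendelian randomization
#'
#' Bundles per-variant summary statistics — the association of each genetic
#' variant with the risk factor (exposure) and with the outcome, each with its
#' standard error — into the unit of analysis used by every estimator in the
#' package. Associations are per effect-allele copy; for binary outcomes the
#' outcome association is a log odds ratio.
#'
#' @param variants a `data.frame` with columns `variant_id`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y` and optionally `effect_allele`, `other_allele`.
#' @param correlation optional J x J matrix of correlations between the
#'   variants (linkage disequilibrium), with rows/columns in dataset order or
#'   named by `variant_id`. Must be symmetric with unit diagonal, entries in
#'   \[-1, 1\], and positive semi-definite within tolerance `1e-8`.
#' @param outcome_scale `"continuous"` or `"log_odds"`. On the log-odds scale,
#'   printed results include the odds-ratio view `exp(estimate)`.
#'
#' @return An object of class `mr_dataset`: the validated variant table with
#'   the correlation matrix and outcome scale stored as attributes.
#' @examples
#' d <- mr_dataset(data.frame(
#'   variant_id = c("rs1", "rs2", "rs3"),
#'   beta_x = c(0.10, 0.08, 0.12), se_x = c(0.01, 0.01, 0.01),
#'   beta_y = c(0.05, 0.04, 0.06), se_y = c(0.01, 0.01, 0.01)))
#' d
#' @seealso [read_mr_dataset()], [orient_variants()], [mr_fit()]
#' @export
mr_dataset <- function(variants,
                       correlation = NULL,
                       outcome_scale = c("continuous", "log_odds")) {
  outcome_scale <- match.arg(outcome_scale)
  stopifnot(is.data.frame(variants))
  required <- c("variant_id", "beta_x", "se_x", "beta_y", "se_y")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$variant_id <- as.character(variants$variant_id)
  for (col in c("beta_x", "se_x", "beta_y", "se_y")) {
    variants[[col]] <- as.numeric(variants[[col]])
  }
  if (!("effect_allele" %in% names(variants))) variants$effect_allele <- NA_character_
  if (!("other_allele" %in% names(variants))) variants$other_allele <- NA_character_
  variants <- variants[, c("variant_id", "effect_allele", "other_allele",
                           "beta_x", "se_x", "beta_y", "se_y")]

  .validate_variants(variants)

  J <- nrow(variants)
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    correlation <- .validate_correlation(correlation, variants$variant_id, J)
  }

  structure(variants,
            correlation = correlation,
            outcome_scale = outcome_scale,
            class = c("mr_dataset", "data.frame"))
}

.validate_variants <- function(v) {
  if (nrow(v) < 1L) stop("dataset must contain at least one variant", call. = FALSE)
  if (any(!nzchar(v$variant_id)) || anyNA(v$variant_id)) {
    stop("variant_id must be non-empty", call. = FALSE)
  }
  dup <- v$variant_id[duplicated(v$variant_id)]
  if (length(dup) > 0L) {
    stop("duplicated variant_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_beta <- !is.finite(v$beta_x) | !is.finite(v$beta_y)
  if (any(bad_beta)) {
    stop("non-finite association estimate for variant(s): ",
         paste(v$variant_id[bad_beta], collapse = ", "), call. = FALSE)
  }
  bad_se <- !is.finite(v$se_x) | !is.finite(v$se_y) | v$se_x <= 0 | v$se_y <= 0
  if (any(bad_se)) {
    stop("standard errors must be positive and finite; offending variant(s): ",
         paste(v$variant_id[bad_se], collapse = ", "), call. = FALSE)
  }
  invisible(v)
}

# Reorders by dimnames when present, then checks symmetry, unit diagonal,
# range and positive semi-definiteness (tolerance 1e-8 on the smallest
# eigenvalue, relative to the largest).
.validate_correlation <- function(rho, ids, J, tol = 1e-8) {
  if (!all(dim(rho) == c(J, J))) {
    stop("correlation matrix must be ", J, " x ", J,
         " to match the number of variants", call. = FALSE)
  }
  if (!is.null(rownames(rho)) && !identical(rownames(rho), ids)) {
    if (!setequal(rownames(rho), ids)) {
      stop("correlation matrix row names do not match variant ids", call. = FALSE)
    }
    rho <- rho[ids, ids, drop = FALSE]
  }
  if (max(abs(rho - t(rho))) > 1e-10) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  rho <- (rho + t(rho)) / 2
  if (max(abs(diag(rho) - 1)) > 1e-10) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  if (any(rho < -1 - 1e-10 | rho > 1 + 1e-10)) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop("correlation matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), "); see build_omega() for regularization",
         call. = FALSE)
  }
  dimnames(rho) <- list(ids, ids)
  rho
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat("Summarized MR dataset: ", nrow(x), " variant(s), outcome scale ",
      attr(x, "outcome_scale"),
      if (!is.null(attr(x, "correlation"))) ", with correlation matrix" else "",
      "\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Subset an MR dataset
#'
#' Row subsetting keeps the correlation matrix and outcome scale consistent:
#' the correlation matrix is subset to the retained variants.
#'
#' @param x an [mr_dataset()].
#' @param i row index (integer, logical, or variant_id character vector).
#' @param ... ignored.
#' @return An `mr_dataset` with the selected variants.
#' @export
`[.mr_dataset` <- function(x, i, ...) {
  df <- as.data.frame(x)
  if (is.character(i)) i <- match(i, df$variant_id)
  out <- df[i, , drop = FALSE]
  rho <- attr(x, "correlation")
  if (!is.null(rho)) rho <- rho[i, i, drop = FALSE]
  mr_dataset(out, correlation = rho, outcome_scale = attr(x, "outcome_scale"))
}

#' @export
as.data.frame.mr_dataset <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "correlation") <- NULL
  attr(x, "outcome_scale") <- NULL
  attr(x, "flipped") <- NULL
  x
}

#' Default column mapping for summary-statistics files
#'
#' The mapping from the package's internal field names to column headers in a
#' delimited summary-statistics file. Any element can be overridden; no single
#' header dialect dominates published summary statistics.
#'
#' @param ... named overrides, e.g. `variant_id = "snp_col"`.
#' @return A named character vector mapping internal names to file headers.
#' @examples
#' mr_columns(beta_x = "bx", se_x = "bxse")
#' @export
mr_columns <- function(...) {
  defaults <- c(variant_id = "snp",
                effect_allele = "effect_allele",
                other_allele = "other_allele",
                beta_x = "beta_exposure",
                se_x = "se_exposure",
                beta_y = "beta_outcome",
                se_y = "se_outcome")
  overrides <- c(...)
  if (length(overrides) > 0L) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown) > 0L) {
      stop("unknown column mapping field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  defaults
}

#' Read a summarized MR dataset from a delimited file
#'
#' Reads per-variant exposure and outcome associations from a CSV/TSV file
#' with a header row. The delimiter is inferred from the file extension
#' (`.tsv`/`.txt` means tab, otherwise comma) unless given. Rows with any
#' missing required field are dropped with a per-row warning; invalid values
#' (e.g. a non-positive standard error) are a validation error naming the
#' variant.
#'
#' @param path path to the file.
#' @param columns column mapping from [mr_columns()].
#' @param delim field delimiter; `NULL` to infer from the extension.
#' @param outcome_scale passed to [mr_dataset()].
#' @param correlation_path optional path to a square CSV of between-variant
#'   correlations whose header row gives the variant ids (reordered to match
#'   the dataset).
#' @return An [mr_dataset()] preserving the file's row order.
#' @export
read_mr_dataset <- function(path,
                            columns = mr_columns(),
                            delim = NULL,
                            outcome_scale = c("continuous", "log_odds"),
                            correlation_path = NULL) {
  outcome_scale <- match.arg(outcome_scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- .infer_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)

  required <- c("variant_id", "beta_x", "se_x", "beta_y", "se_y")
  for (field in required) {
    if (!(columns[[field]] %in% names(raw))) {
      stop("column '", columns[[field]], "' (mapped to ", field,
           ") not found in ", path, call. = FALSE)
    }
  }
  out <- data.frame(variant_id = as.character(raw[[columns[["variant_id"]]]]),
                    stringsAsFactors = FALSE)
  for (field in c("beta_x", "se_x", "beta_y", "se_y")) {
    out[[field]] <- as.numeric(raw[[columns[[field]]]])
  }
  for (field in c("effect_allele", "other_allele")) {
    col <- columns[[field]]
    out[[field]] <- if (col %in% names(raw)) as.character(raw[[col]]) else NA_character_
  }

  incomplete <- !stats::complete.cases(out[, required])
  if (any(incomplete)) {
    warning("dropped ", sum(incomplete), " row(s) with missing fields: ",
            paste(sprintf("row %d (%s)", which(incomplete),
                          ifelse(is.na(out$variant_id[incomplete]) |
                                   !nzchar(out$variant_id[incomplete]),
                                 "<no id>", out$variant_id[incomplete])),
                  collapse = "; "),
            call. = FALSE)
    out <- out[!incomplete, , drop = FALSE]
  }

  rho <- if (!is.null(correlation_path)) read_mr_correlation(correlation_path) else NULL
  mr_dataset(out, correlation = rho, outcome_scale = outcome_scale)
}

#' Read a between-variant correlation matrix from CSV
#'
#' @param path square CSV whose header row holds variant ids.
#' @return A numeric matrix with variant ids as dimnames.
#' @export
read_mr_correlation <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  rownames(m) <- colnames(m)
  m
}

.infer_delim <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Write a summarized MR dataset to a delimited file
#'
#' Numeric fields are written with 17 significant digits so that a
#' read/write round trip recovers them to within 1e-12.
#'
#' @param x an [mr_dataset()].
#' @param path output path; extension selects the delimiter as in
#'   [read_mr_dataset()].
#' @param columns column mapping giving the output headers.
#' @param delim field delimiter; `NULL` to infer.
#' @return `path`, invisibly.
#' @export
write_mr_dataset <- function(x, path, columns = mr_columns(), delim = NULL) {
  stopifnot(inherits(x, "mr_dataset"))
  if (is.null(delim)) delim <- .infer_delim(path)
  df <- as.data.frame(x)
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL,
                    .id = df$variant_id)
  names(out) <- columns[["variant_id"]]
  out[[columns[["effect_allele"]]]] <- df$effect_allele
  out[[columns[["other_allele"]]]] <- df$other_allele
  for (field in c("beta_x", "se_x", "beta_y", "se_y")) {
    out[[columns[[field]]]] <- sprintf("%.17g", df[[field]])
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Orient variants with respect to the risk-factor-increasing allele
#'
#' Recodes each variant so that its association with the risk factor is
#' non-negative: for a flipped variant both `beta_x` and `beta_y` are negated
#' and the effect/other alleles are swapped; standard errors are unchanged.
#' When a correlation matrix is present, the off-diagonal entries involving a
#' flipped variant change sign (recoding an allele negates its allele-count
#' correlations with the other variants).
#'
#' The IVW estimate is unaffected by orientation, but the MR-Egger intercept
#' and slope are not: orientation fixes the definition of directional
#' pleiotropy to the risk-factor-increasing allele, so it should be applied
#' before any MR-Egger analysis. A variant whose risk-factor association is
#' exactly zero cannot be oriented; it is left unchanged with a warning (such
#' a variant also has an undefined ratio estimate and is excluded from the
#' median estimators).
#'
#' @param x an [mr_dataset()].
#' @return The oriented `mr_dataset`, with the ids of flipped variants in
#'   `attr(, "flipped")` and of un-orientable (zero `beta_x`) variants in
#'   `attr(, "unoriented")`.
#' @examples
#' d <- mr_dataset(data.frame(
#'   variant_id = c("rs1", "rs2"),
#'   beta_x = c(-0.1, 0.2), se_x = c(0.01, 0.01),
#'   beta_y = c(-0.3, 0.1), se_y = c(0.05, 0.05)))
#' attr(orient_variants(d), "flipped")
#' @export
orient_variants <- function(x) {
  stopifnot(inherits(x, "mr_dataset"))
  df <- as.data.frame(x)
  zero <- df$beta_x == 0
  if (any(zero)) {
    warning("variant(s) with beta_x = 0 cannot be oriented and are left ",
            "unchanged: ", paste(df$variant_id[zero], collapse = ", "),
            call. = FALSE)
  }
  flip <- df$beta_x < 0
  df$beta_x[flip] <- -df$beta_x[flip]
  df$beta_y[flip] <- -df$beta_y[flip]
  ea <- df$effect_allele[flip]
  df$effect_allele[flip] <- df$other_allele[flip]
  df$other_allele[flip] <- ea

  rho <- attr(x, "correlation")
  if (!is.null(rho) && any(flip)) {
    s <- ifelse(flip, -1, 1)
    rho <- rho * tcrossprod(s)   # negates rows/cols of flipped variants, diag intact
  }

  out <- mr_dataset(df, correlation = rho,
                    outcome_scale = attr(x, "outcome_scale"))
  attr(out, "flipped") <- df$variant_id[flip]
  attr(out, "unoriented") <- df$variant_id[zero]
  out
}

#' Write estimator results to a delimited table or JSON
#'
#' Serializes one or more fitted objects ([mr_fit()] results, and optionally
#' [mr_diagnostics()] reports via their own writer) into a flat results table
#' with columns `method`, `estimate`, `se`, `ci_lower`, `ci_upper`,
#' `ci_level`, `p_value`, `variance_model`, `sigma_hat`, `n_variants`.
#' MR-Egger fits contribute two rows (`egger` slope and `egger_intercept`).
#' Numbers are written with 17 significant digits (round trip to 1e-12).
#'
#' @param results a single fit or a list of fits.
#' @param path output path; `.json` selects JSON, otherwise CSV.
#' @param format `"csv"` or `"json"`; `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path, format = NULL) {
  if (inherits(results, "mr_fit")) results <- list(results)
  if (length(results) == 0L) stop("no results to write", call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  tab <- do.call(rbind, lapply(results, as.data.frame))
  rownames(tab) <- NULL
  if (format == "json") {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    out <- tab
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(z) sprintf("%.17g", z))
    utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
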