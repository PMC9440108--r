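# Fossil reconstruction: apply a calibrated method to a fossil
# sequence, with taxon matching, coverage accounting and sample-specific
# errors from bootstrap validation.

#' Reconstruct past environments from a fossil sequence
#'
#' Applies the specified transfer-function method to each target
#' variable. Fossil taxa are matched to training taxa by id; unmatched
#' taxa are dropped with a warning, and any sample losing more than half
#' of its abundance to unmatched taxa is flagged. With
#' \code{with_errors = TRUE} a bootstrap validation supplies a
#' sample-specific +/-1 SD error per target.
#'
#' @param spec a \code{\link{method_spec}}.
#' @param training modern \code{\link{taxon_table}} (percentages).
#' @param env an \code{\link{env_table}} aligned with the training set.
#' @param fossil fossil \code{\link{taxon_table}} (percentages, with
#'   ages).
#' @param targets environmental variable names to reconstruct.
#' @param with_errors compute sample-specific errors (default TRUE).
#' @param n_boot bootstrap cycles for the errors.
#' @param seed integer seed; per-target child seeds are derived.
#' @return a \code{reconstruction_series}: data.frame with
#'   \code{age_calBP}, one prediction column per target, one
#'   \code{<target>_sd} column per target when errors are requested, and
#'   a \code{min_dissim} analogue-quality column. Attributes:
#'   \code{coverage} (matched-abundance fraction per sample),
#'   \code{flagged} (samples under 50 percent coverage), \code{spec},
#'   \code{cv} (per-target \code{crossval_stats}).
#' @export
reconstruct <- function(spec, training, env, fossil, targets,
                        with_errors = TRUE, n_boot = 1000, seed = 1) {
  stopifnot(inherits(spec, "method_spec"))
  check_aligned(training, env)
  missing_t <- setdiff(targets, env$var_names)
  if (length(missing_t)) stop("unknown target(s): ", paste(missing_t, collapse = ", "))
  ytrain <- as_abund(training)
  yfoss <- as_abund(fossil)
  shared <- intersect(colnames(ytrain), colnames(yfoss))
  if (!length(shared)) stop("fossil and training sets share no taxa")
  unmatched <- setdiff(colnames(yfoss), colnames(ytrain))
  coverage <- rowSums(yfoss[, shared, drop = FALSE]) / rowSums(yfoss)
  if (length(unmatched)) {
    warning(sprintf("%d fossil taxa unmatched in training set (%s); mean abundance coverage %.1f%%",
                    length(unmatched), paste(head(unmatched, 5), collapse = ", "),
                    100 * mean(coverage)))
  }
  flagged <- (rownames(yfoss) %||% seq_len(nrow(yfoss)))[coverage < 0.5]
  if (length(flagged)) {
    warning("sample(s) losing > 50% abundance to unmatched taxa: ",
            paste(head(flagged, 10), collapse = ", "))
  }
  yfoss_m <- yfoss[, shared, drop = FALSE]
  ages <- if (inherits(fossil, "taxon_table") && !is.null(fossil$ages)) fossil$ages
          else seq_len(nrow(yfoss))
  out <- data.frame(age_calBP = ages)
  cvs <- list()
  for (tg in targets) {
    x <- env$values[, tg]
    out[[tg]] <- as.numeric(fit_predict(spec, ytrain, x, yfoss_m))
    if (with_errors) {
      cv <- bootstrap_validate(spec, ytrain, x, n_boot = n_boot,
                               seed = derive_seed(seed, paste0("recon:", tg)),
                               fossil = yfoss_m)
      out[[paste0(tg, "_sd")]] <- if (!is.null(cv$fossil)) cv$fossil$error
                                  else rep(cv$rmsep, nrow(out))
      cvs[[tg]] <- cv
    }
  }
  out$min_dissim <- apply(cross_dissimilarity(yfoss_m, ytrain, spec$metric), 1, min)
  rownames(out) <- rownames(yfoss) %||% NULL
  structure(out, coverage = coverage, flagged = flagged, spec = spec,
            cv = if (length(cvs)) cvs, seed = seed,
            class = c("reconstruction_series", "data.frame"))
}

#' @export
print.reconstruction_series <- function(x, ...) {
  tg <- setdiff(names(x), c("age_calBP", "min_dissim",
                            grep("_sd$", names(x), value = TRUE)))
  cat(sprintf("reconstruction_series: %d samples, targets: %s\n",
              nrow(x), paste(tg, collapse = ", ")))
  invisible(x)
}

#' Write a reconstruction and its model card
#'
#' The series goes to CSV (age, one column per target, one +/-1 SD
#' column per target, analogue-quality column); the model card - method,
#' parameters, seed and cross-validation statistics - to a JSON sidecar
#' next to it.
#'
#' @param recon a \code{reconstruction_series}.
#' @param path CSV output path; the model card is written to
#'   \code{<path>.model.json}.
#' @export
write_reconstruction_csv <- function(recon, path) {
  utils::write.csv(as.data.frame(recon), path, row.names = FALSE)
  spec <- attr(recon, "spec")
  cvs <- attr(recon, "cv")
  card <- list(
    method = unclass(spec),
    seed = attr(recon, "seed"),
    n_samples = nrow(recon),
    mean_coverage = mean(attr(recon, "coverage")),
    flagged_samples = attr(recon, "flagged"),
    cv = if (!is.null(cvs)) lapply(cvs, function(cv) {
      list(rmsep = cv$rmsep, r2 = cv$r2, avg_bias = cv$avg_bias,
           max_bias = cv$max_bias, n_boot = cv$n_boot)
    })
  )
  jsonlite::write_json(card, paste0(path, ".model.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
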