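#' Neural-mass variant of a field model
#'
#' Returns the same parameter set with the mass-limit flag set: the transit
#' time is structurally zero (infinite conduction velocity collapses the
#' patch to a point source) and is removed from the free-parameter set, so
#' the variant has one fewer estimated parameter. An alternative route --
#' keeping the field structure but shrinking the transit time with a very
#' precise prior -- is available via `shrink`; under log-scaling the transit
#' time can never reach zero exactly, so the structural flag is the default.
#'
#' @param params an `nf_params` object (field variant).
#' @param shrink if `TRUE`, return instead a list with the unchanged field
#'   `params` and a `prior` whose transit-time log-scaling is pinned near a
#'   large negative mean by precision `1e8`.
#' @return an `nf_params` object (or a list of `params` and `prior` when
#'   `shrink = TRUE`).
#' @export
make_mass_variant <- function(params, shrink = FALSE) {
  if (shrink) {
    prior <- nf_prior(params)
    i <- match("upsilon", names(prior$mean))
    prior$mean[i] <- -8      # e^-8 ~ 3e-4 of the prior transit time
    prior$precision[i, i] <- 1e8
    return(list(params = params, prior = prior))
  }
  params$mass_limit <- TRUE
  params
}

#' Bayesian model comparison by free energy
#'
#' Collects the free energies (log-evidence approximations) of a set of
#' posteriors fitted to the same data, sorts them, and reports pairwise
#' differences. A margin of three nats or more over the runner-up is flagged
#' as strong evidence.
#'
#' @param posteriors list of `nf_posterior` objects (all fitted to the same
#'   data), or several posteriors as separate arguments.
#' @param names optional model names; defaults to the posteriors' model
#'   labels, made unique.
#' @return object of class `nf_comparison`: `table` (model, F, sorted
#'   decreasing), `deltas` (antisymmetric matrix of F differences),
#'   `best`, and `strong` (logical).
#' @export
compare_models <- function(posteriors, names = NULL) {
  if (inherits(posteriors, "nf_posterior")) posteriors <- list(posteriors)
  stopifnot(length(posteriors) >= 1,
            all(vapply(posteriors, inherits, logical(1), "nf_posterior")))
  if (length(posteriors) > 1) {
    fp <- vapply(posteriors, function(p) p$data_fingerprint, numeric(6))
    if (any(abs(fp - fp[, 1]) > 1e-9 * (1 + abs(fp[, 1])))) {
      stop("posteriors were not fitted to the same data")
    }
  }
  if (is.null(names)) {
    names <- make.unique(vapply(posteriors, `[[`, character(1), "model"))
  }
  F <- vapply(posteriors, `[[`, numeric(1), "F")
  ord <- order(F, decreasing = TRUE)
  deltas <- outer(F, F, `-`)
  dimnames(deltas) <- list(names, names)
  strong <- length(F) > 1 && (F[ord[1]] - F[ord[2]] >= 3)
  structure(list(table = data.frame(model = names[ord], F = F[ord]),
                 deltas = deltas, best = names[ord[1]], strong = strong),
            class = "nf_comparison")
}

#' @export
print.nf_comparison <- function(x, ...) {
  cat("Bayesian model comparison (free energy, nats)\n")
  print(x$table, row.names = FALSE)
  if (nrow(x$table) > 1) {
    cat(sprintf("best: %s (margin %.2f nats%s)\n", x$best,
                x$table$F[1] - x$table$F[2],
                if (x$strong) ", strong evidence" else ""))
  } else {
    cat(sprintf("single model: %s\n", x$best))
  }
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param x an `nf_comparison`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(x, path) {
  stopifnot(inherits(x, "nf_comparison"))
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
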