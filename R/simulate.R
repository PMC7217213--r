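#' Specify a synthetic component network
#'
#' Defines the generative truth for [simulate_network()]: component effects
#' on the additive (log odds-ratio) scale, the treatment combinations in
#' play, per-study arm counts, sampling-error scale and between-study
#' variance.
#'
#' @param beta named numeric vector of true component effects.
#' @param treatments character vector of treatment labels composed from the
#'   components with `sep` (an `inactive` label may appear without being a
#'   component).
#' @param k_studies number of studies.
#' @param arms integer vector of per-study arm counts, recycled to
#'   `k_studies`.
#' @param se_range positive range the two-arm contrast standard errors are
#'   drawn from (arm-level sampling standard deviations are
#'   `runif(se_range) / sqrt(2)`, so multi-arm standard errors decompose
#'   exactly into arm variances).
#' @param tau2 true between-study variance (common across comparisons).
#' @param inactive optional inactive treatment label.
#' @param interactions optional named numeric vector of true interaction
#'   effects, names like `"A*B"`; added on top of the additive truth for
#'   treatments containing all named components.
#' @param designs optional list of character vectors fixing each study's
#'   treatment set (recycled); by default sets are sampled at random.
#' @param sep component separator in treatment labels.
#' @param seed integer seed; the generator is seeded once per simulated
#'   network, so equal seeds give byte-identical networks.
#' @return an object of class `sim_spec`.
#' @examples
#' spec <- sim_spec(beta = c(A = 1, B = 0.5),
#'                  treatments = c("A", "B", "A+B", "placebo"),
#'                  inactive = "placebo", k_studies = 10, seed = 42)
#' net <- simulate_network(spec)
#' @export
sim_spec <- function(beta, treatments, k_studies = 20L, arms = 2L,
                     se_range = c(0.2, 0.5), tau2 = 0, inactive = NULL,
                     interactions = NULL, designs = NULL, sep = "+",
                     seed = 1L) {
  stopifnot(is.numeric(beta), !is.null(names(beta)), all(nzchar(names(beta))),
            is.character(treatments), length(treatments) >= 2L,
            k_studies >= 1L, all(arms >= 2L),
            length(se_range) == 2L, se_range[1] > 0,
            se_range[2] >= se_range[1], tau2 >= 0)
  comps <- build_combination(treatments, sep = sep, inactive = inactive)
  missing <- setdiff(names(beta), comps$components)
  extra <- setdiff(comps$components, names(beta))
  if (length(missing) || length(extra)) {
    rlang::abort(paste0("`beta` must name exactly the parsed components; ",
                        "unused: ", paste(missing, collapse = ", "),
                        "; unnamed: ", paste(extra, collapse = ", ")),
                 class = "cnma_validation_error")
  }
  if (!is.null(interactions)) {
    stopifnot(is.numeric(interactions), !is.null(names(interactions)))
    comps <- add_interactions(comps, names(interactions))
  }
  if (!is.null(designs)) {
    stopifnot(is.list(designs))
    ok <- vapply(designs, function(x) all(x %in% treatments) &&
                   length(unique(x)) >= 2L, logical(1))
    if (!all(ok)) {
      rlang::abort("each design must list >= 2 known treatments",
                   class = "cnma_validation_error")
    }
  }
  structure(
    list(beta = beta, treatments = treatments, comps = comps,
         k_studies = as.integer(k_studies),
         arms = rep_len(as.integer(arms), k_studies),
         se_range = as.numeric(se_range), tau2 = tau2,
         inactive = inactive, interactions = interactions,
         designs = designs, sep = sep, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Simulate a contrast network with known component truth
#'
#' True treatment effects are `theta* = C [beta; gamma]` (additive plus any
#' interaction truth). Heterogeneity is generated at the arm level: each
#' study draws independent arm effects `u_t ~ N(0, tau2 / 2)` and each
#' contrast receives `u_t1 - u_t2`, which realises the common-`tau2`
#' contrast-level random-effects model (within-study covariance
#' `tau2 * 0.5 B B'`) while keeping within-study consistency exact.
#' Sampling error is likewise arm-level, so the standard errors of a
#' multi-arm study decompose exactly into arm variances (the contract of
#' [adjust_multiarm()]).
#'
#' @param spec a [sim_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return an `nma_network` with an extra element `truth` (true `beta`,
#'   `theta`, `tau2`, the component structure, and the seed used).
#' @export
simulate_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  seed <- as.integer(seed %||% spec$seed)
  set.seed(seed)

  C <- spec$comps$C
  truth_coef <- c(spec$beta[setdiff(colnames(C), names(spec$interactions))],
                  spec$interactions)[colnames(C)]
  theta <- drop(C %*% truth_coef)
  names(theta) <- rownames(C)

  for (attempt in seq_len(100L)) {
    rows <- vector("list", spec$k_studies)
    for (i in seq_len(spec$k_studies)) {
      p <- min(spec$arms[[i]], length(spec$treatments))
      trts <- if (!is.null(spec$designs)) {
        spec$designs[[(i - 1L) %% length(spec$designs) + 1L]]
      } else {
        sample(spec$treatments, p)
      }
      trts <- sort(unique(trts), method = "radix")
      p <- length(trts)
      u <- stats::rnorm(p, 0, sqrt(spec$tau2 / 2))
      a_sd <- stats::runif(p, spec$se_range[1], spec$se_range[2]) / sqrt(2)
      e <- stats::rnorm(p, 0, a_sd)
      idx <- utils::combn(p, 2L)
      rows[[i]] <- tibble::tibble(
        study = sprintf("study_%04d", i),
        treat1 = trts[idx[1L, ]], treat2 = trts[idx[2L, ]],
        effect = unname(theta[treat1] - theta[treat2]) +
          (u[idx[1L, ]] - u[idx[2L, ]]) + (e[idx[1L, ]] - e[idx[2L, ]]),
        se = sqrt(a_sd[idx[1L, ]]^2 + a_sd[idx[2L, ]]^2)
      )
    }
    net <- nma_network(dplyr::bind_rows(rows))
    if (n_subnets(net) == 1L || !is.null(spec$designs)) break
  }
  net$truth <- list(beta = truth_coef, theta = theta, tau2 = spec$tau2,
                    comps = spec$comps, seed = seed)
  net
}
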