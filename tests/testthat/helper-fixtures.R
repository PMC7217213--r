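# Shared fixtures built in code.

# the 6-study, 5-treatment hypothetical network (2-arm studies only)
tab1_data <- function(d = c(1, 2, 0, 1, 1, 1), se = rep(1, 6)) {
  tibble::tibble(
    study  = paste0("Study ", 1:6),
    treat1 = c("A", "A", "A+B", "A+B", "B+C", "A"),
    treat2 = c("A+B", "A+B+C", "B+C", "A+B+C", "A+B+C", "placebo"),
    effect = d, se = se
  )
}

tab1_treatments <- c("A", "A+B", "A+B+C", "B+C", "placebo")

tab1_network <- function(d = c(1, 2, 0, 1, 1, 1), se = rep(1, 6)) {
  nma_network(tab1_data(d, se), treatments = tab1_treatments)
}

# three mutually disconnected two-arm studies sharing components A, B, C
disconnected3_network <- function(d = c(0.1, -0.2, 0.3), se = rep(1, 3)) {
  nma_network(
    tibble::tibble(
      study = c("s1", "s2", "s3"),
      treat1 = c("A", "B", "A+B"), treat2 = c("B+C", "A+C", "C"),
      effect = d, se = se),
    treatments = c("A", "B", "C", "B+C", "A+C", "A+B"))
}

# Random connected network with mixed 2-/3-arm studies. Arm-level sampling
# standard deviations guarantee that multi-arm contrast variances decompose
# exactly into arm variances.
random_network <- function(n_treat = sample(3:8, 1), k_extra = sample(2:12, 1),
                           treatments = NULL, p3_prob = 0.3,
                           sd_range = c(0.3, 0.8)) {
  treatments <- treatments %||% paste0("T", seq_len(n_treat))
  n <- length(treatments)
  rows <- list()
  add_study <- function(id, trts) {
    trts <- sort(trts, method = "radix")
    a_sd <- stats::runif(length(trts), sd_range[1], sd_range[2])
    idx <- utils::combn(length(trts), 2L)
    tibble::tibble(
      study = id, treat1 = trts[idx[1L, ]], treat2 = trts[idx[2L, ]],
      effect = stats::rnorm(ncol(idx)),
      se = sqrt(a_sd[idx[1L, ]]^2 + a_sd[idx[2L, ]]^2))
  }
  ord <- sample(treatments)
  for (i in 2:n) {   # spanning tree keeps the network connected
    rows[[length(rows) + 1L]] <-
      add_study(sprintf("tree_%02d", i), c(ord[i], ord[sample(i - 1L, 1L)]))
  }
  for (j in seq_len(k_extra)) {
    p <- if (n >= 3 && stats::runif(1) < p3_prob) 3L else 2L
    rows[[length(rows) + 1L]] <-
      add_study(sprintf("xtra_%02d", j), sample(treatments, p))
  }
  nma_network(dplyr::bind_rows(rows))
}

# random network over combination treatments with full-rank additive design
random_component_network <- function(max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    n_comp <- sample(2:4, 1)
    comps_pool <- LETTERS[seq_len(n_comp)]
    subsets <- unlist(lapply(seq_len(min(3L, n_comp)), function(s)
      utils::combn(comps_pool, s, paste, collapse = "+")), use.names = FALSE)
    trts <- unique(c(sample(subsets, min(length(subsets), sample(3:6, 1))),
                     "placebo"))
    if (length(trts) < 3) next
    net <- random_network(treatments = trts)
    comps <- build_combination(net, inactive = "placebo")
    Xa <- build_incidence(net) %*% comps$C[net$treatments, , drop = FALSE]
    if (qr(Xa)$rank == ncol(Xa)) return(list(network = net, comps = comps))
  }
  stop("could not generate a full-rank component network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
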