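#' Build a contrast-level network meta-analysis dataset
#'
#' Validates contrast-level data (one row per pairwise comparison) and
#' assembles the network object used by all fitting functions. The effect
#' convention throughout is `effect = treat1 - treat2` on an additive scale
#' (log odds ratio, log risk ratio, mean difference, ...).
#'
#' A `p`-arm study must contribute all `p * (p - 1) / 2` pairwise rows.
#' Standard errors of multi-arm studies are adjusted at construction time so
#' that, treating the adjusted contrasts as independent, each study
#' contributes the same information as a joint arm-level weighted model (see
#' [adjust_multiarm()]).
#'
#' @param data data frame with one row per pairwise comparison. Column names
#'   are auto-detected among common aliases (`study`/`studlab`,
#'   `treat1`, `treat2`, `effect`/`TE`, `se`/`seTE`) or can be given
#'   explicitly.
#' @param study,treat1,treat2,effect,se optional bare column names
#'   overriding auto-detection.
#' @param treatments,studies optional character vectors fixing the treatment
#'   and study ordering; default is stable lexicographic order.
#' @return an object of class `nma_network`: a list with the validated
#'   contrast tibble (`$contrasts`, including the multi-arm adjusted standard
#'   error `se_adj`), the ordered `treatments` and `studies`, the per-study
#'   arm counts `arms`, and the counts `n` (treatments), `m` (comparisons),
#'   `k` (studies) and `n_a` (total arms).
#' @examples
#' dat <- tibble::tibble(
#'   study = c("s1", "s2"), treat1 = c("A", "A+B"),
#'   treat2 = c("placebo", "A"), effect = c(0.5, 0.3), se = c(0.2, 0.25)
#' )
#' net <- nma_network(dat)
#' net$n
#' @seealso [read_contrasts()], [contrasts_from_arms()]
#' @export
nma_network <- function(data, study = NULL, treat1 = NULL, treat2 = NULL,
                        effect = NULL, se = NULL,
                        treatments = NULL, studies = NULL) {
  stopifnot(is.data.frame(data))
  pick <- function(quo, aliases, what) {
    if (!rlang::quo_is_null(quo)) {
      nm <- rlang::as_name(quo)
      if (!nm %in% names(data)) {
        rlang::abort(paste0("column `", nm, "` not found in `data`"),
                     class = "cnma_format_error")
      }
      return(nm)
    }
    hit <- intersect(aliases, names(data))
    if (length(hit) == 0L) {
      rlang::abort(
        paste0("no column for ", what, " (looked for: ",
               paste(aliases, collapse = ", "), ")"),
        class = "cnma_format_error")
    }
    hit[[1L]]
  }
  nm_study  <- pick(rlang::enquo(study),  c("study", "studlab"), "study label")
  nm_t1     <- pick(rlang::enquo(treat1), c("treat1", "t1"), "first treatment")
  nm_t2     <- pick(rlang::enquo(treat2), c("treat2", "t2"), "second treatment")
  nm_effect <- pick(rlang::enquo(effect), c("effect", "TE", "te"), "effect estimate")
  nm_se     <- pick(rlang::enquo(se),     c("se", "seTE", "sete"), "standard error")

  d <- tibble::tibble(
    study  = as.character(data[[nm_study]]),
    treat1 = as.character(data[[nm_t1]]),
    treat2 = as.character(data[[nm_t2]]),
    effect = as.numeric(data[[nm_effect]]),
    se     = as.numeric(data[[nm_se]])
  )
  if (anyNA(d)) {
    rlang::abort("missing values in study/treatment/effect/se columns",
                 class = "cnma_validation_error")
  }
  if (any(d$se <= 0)) {
    rlang::abort("all standard errors must be > 0",
                 class = "cnma_validation_error")
  }
  if (any(d$treat1 == d$treat2)) {
    rlang::abort("treat1 and treat2 must differ within a comparison",
                 class = "cnma_validation_error")
  }
  pair_key <- paste(d$study,
                    pmin(d$treat1, d$treat2), pmax(d$treat1, d$treat2),
                    sep = "\r")
  if (anyDuplicated(pair_key)) {
    dup <- d[duplicated(pair_key), , drop = FALSE]
    rlang::abort(
      paste0("duplicated comparison within a study: ",
             paste(unique(paste0(dup$study, ": ", dup$treat1, " vs ", dup$treat2)),
                   collapse = "; ")),
      class = "cnma_validation_error")
  }

  all_treats <- sort(unique(c(d$treat1, d$treat2)), method = "radix")
  if (is.null(treatments)) {
    treatments <- all_treats
  } else {
    treatments <- as.character(treatments)
    if (!setequal(treatments, all_treats) || anyDuplicated(treatments)) {
      rlang::abort("`treatments` must be a permutation of the observed treatment labels",
                   class = "cnma_validation_error")
    }
  }
  all_studies <- sort(unique(d$study), method = "radix")
  if (is.null(studies)) {
    studies <- all_studies
  } else {
    studies <- as.character(studies)
    if (!setequal(studies, all_studies) || anyDuplicated(studies)) {
      rlang::abort("`studies` must be a permutation of the observed study labels",
                   class = "cnma_validation_error")
    }
  }

  d <- d[order(match(d$study, studies),
               match(d$treat1, treatments),
               match(d$treat2, treatments)), , drop = FALSE]

  # p-arm studies must contribute the complete set of p(p-1)/2 comparisons
  arms <- vapply(split(d[c("treat1", "treat2")], d$study),
                 function(x) length(unique(c(x$treat1, x$treat2))),
                 integer(1))[studies]
  m_per_study <- table(factor(d$study, levels = studies))
  expected <- arms * (arms - 1L) / 2L
  bad <- which(as.integer(m_per_study) != expected)
  if (length(bad)) {
    rlang::abort(
      paste0("study ", studies[bad[1L]], " has ", arms[bad[1L]],
             " arms but ", m_per_study[bad[1L]], " comparisons; a p-arm study",
             " must contribute all p*(p-1)/2 pairwise comparisons"),
      class = "cnma_validation_error")
  }

  net <- structure(
    list(
      contrasts  = tibble::as_tibble(d),
      treatments = treatments,
      studies    = studies,
      arms       = stats::setNames(as.integer(arms), studies),
      n          = length(treatments),
      m          = nrow(d),
      k          = length(studies),
      n_a        = sum(arms)
    ),
    class = "nma_network"
  )
  adjust_multiarm(net)
}

#' @export
print.nma_network <- function(x, ...) {
  cat("Network meta-analysis data: ",
      x$n, " treatments, ", x$k, " studies, ",
      x$m, " pairwise comparisons (", x$n_a, " arms)\n", sep = "")
  multi <- sum(x$arms > 2)
  if (multi) cat(multi, "multi-arm", if (multi == 1) "study\n" else "studies\n")
  print(x$contrasts, ...)
  invisible(x)
}

#' @method as_tibble nma_network
#' @export
as_tibble.nma_network <- function(x, ...) x$contrasts

#' Read contrast-level data from a delimited text file
#'
#' Expects a header row; the delimiter is auto-detected among comma, tab and
#' semicolon. Columns are matched as in [nma_network()] (`study`/`studlab`,
#' `treat1`, `treat2`, `effect`/`TE`, `se`/`seTE`).
#'
#' @param file path to a CSV/TSV file.
#' @param ... passed on to [nma_network()] (e.g. `treatments`).
#' @return an `nma_network` object.
#' @export
read_contrasts <- function(file, ...) {
  nma_network(read_delim_auto(file), ...)
}

read_delim_auto <- function(file) {
  header <- readLines(file, n = 1L)
  if (length(header) == 0L) {
    rlang::abort("empty input file", class = "cnma_format_error")
  }
  counts <- c(`,` = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              `\t` = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              `;` = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))))
  sep <- names(counts)[which.max(counts)]
  utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Convert arm-level binary outcome data to a contrast network
#'
#' Builds log odds ratios and their standard errors for every within-study
#' treatment pair. If any cell of a 2x2 table is zero, 0.5 is added to all
#' four cells of that comparison (per-comparison continuity correction).
#'
#' @param arms data frame with columns `study`, `treat` (or `treatment`),
#'   `events`, `n`; one row per study arm.
#' @param ... passed on to [nma_network()].
#' @return an `nma_network` object on the log odds-ratio scale.
#' @examples
#' arms <- tibble::tibble(
#'   study = c("s1", "s1"), treat = c("A", "P"),
#'   events = c(15, 5), n = c(20, 20)
#' )
#' contrasts_from_arms(arms)$contrasts
#' @export
contrasts_from_arms <- function(arms, ...) {
  stopifnot(is.data.frame(arms))
  nm_treat <- intersect(c("treat", "treatment"), names(arms))
  need <- c("study", "events", "n")
  if (length(nm_treat) == 0L || !all(need %in% names(arms))) {
    rlang::abort("arm-level data needs columns study, treat(ment), events, n",
                 class = "cnma_format_error")
  }
  a <- tibble::tibble(
    study  = as.character(arms$study),
    treat  = as.character(arms[[nm_treat[[1L]]]]),
    events = as.numeric(arms$events),
    n      = as.numeric(arms$n)
  )
  if (anyNA(a)) {
    rlang::abort("missing values in arm-level data", class = "cnma_validation_error")
  }
  if (any(a$events < 0)) {
    rlang::abort("events must be >= 0", class = "cnma_validation_error")
  }
  if (any(a$n <= a$events)) {
    rlang::abort("each arm needs n > events (at least one non-event)",
                 class = "cnma_validation_error")
  }
  if (anyDuplicated(paste(a$study, a$treat, sep = "\r"))) {
    rlang::abort("duplicated treatment arm within a study",
                 class = "cnma_validation_error")
  }

  per_study <- split(a, a$study)
  if (any(vapply(per_study, nrow, integer(1)) < 2L)) {
    rlang::abort("every study needs at least two arms",
                 class = "cnma_validation_error")
  }
  rows <- purrr::map_dfr(per_study, function(s) {
    s <- s[order(s$treat, method = "radix"), , drop = FALSE]
    idx <- utils::combn(nrow(s), 2L)
    purrr::map_dfr(seq_len(ncol(idx)), function(j) {
      i1 <- idx[1L, j]; i2 <- idx[2L, j]
      e1 <- s$events[i1]; f1 <- s$n[i1] - e1
      e2 <- s$events[i2]; f2 <- s$n[i2] - e2
      if (min(e1, f1, e2, f2) == 0) {
        e1 <- e1 + 0.5; f1 <- f1 + 0.5; e2 <- e2 + 0.5; f2 <- f2 + 0.5
      }
      tibble::tibble(
        study = s$study[[1L]], treat1 = s$treat[i1], treat2 = s$treat[i2],
        effect = log((e1 / f1) / (e2 / f2)),
        se = sqrt(1 / e1 + 1 / f1 + 1 / e2 + 1 / f2)
      )
    })
  })
  nma_network(rows, ...)
}

#' Read arm-level binary data from a delimited text file
#'
#' @inheritParams read_contrasts
#' @return an `nma_network` object (log odds-ratio scale).
#' @export
read_arms <- function(file, ...) {
  contrasts_from_arms(read_delim_auto(file), ...)
}
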