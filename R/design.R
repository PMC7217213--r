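#' Edge-vertex incidence matrix of the comparison network
#'
#' One row per pairwise comparison with `+1` in the column of `treat1`,
#' `-1` in the column of `treat2`, zero elsewhere. `B` encodes the network
#' topology; `B %*% theta` maps treatment effects to contrasts and
#' `t(B) %*% W %*% B` is the weighted graph Laplacian.
#'
#' @param network an `nma_network` object.
#' @return an `m x n` matrix with dimnames (comparison labels, treatments).
#' @export
build_incidence <- function(network) {
  stopifnot(inherits(network, "nma_network"))
  d <- network$contrasts
  B <- matrix(0, network$m, network$n,
              dimnames = list(paste0(d$study, ": ", d$treat1, " vs ", d$treat2),
                              network$treatments))
  B[cbind(seq_len(network$m), match(d$treat1, network$treatments))] <- 1
  B[cbind(seq_len(network$m), match(d$treat2, network$treatments))] <- -1
  B
}

#' Component structure of combination treatments
#'
#' Parses treatment labels into components and builds the `n x c`
#' combination matrix `C`: entry `C[i, j]` is the multiplicity (usually 0/1)
#' with which component `j` contributes to treatment `i`. An inactive
#' treatment (e.g. placebo) is not counted as a component; its row is all
#' zero, so comparisons against it estimate net component effects.
#'
#' @param treatments character vector of treatment labels (or an
#'   `nma_network`, whose treatment set is used).
#' @param sep separator between components inside a label (default `"+"`);
#'   surrounding whitespace is stripped, labels are case-sensitive.
#' @param inactive optional label of the inactive treatment; must not itself
#'   contain the separator.
#' @param dose optional named list of dose codings overriding the parsed row
#'   of a treatment, e.g. `list("A_double" = c(A = 2))` states that
#'   `A_double` acts like a doubled dose of component `A`.
#' @return an object of class `component_structure`: list with the ordered
#'   `components`, the matrix `C`, `inactive`, and `sep`.
#' @examples
#' cs <- build_combination(c("A", "A+B", "A+B+C", "B+C", "placebo"),
#'                         inactive = "placebo")
#' cs$C
#' @export
build_combination <- function(treatments, sep = "+", inactive = NULL,
                              dose = NULL) {
  if (inherits(treatments, "nma_network")) treatments <- treatments$treatments
  treatments <- as.character(treatments)
  stopifnot(is.character(sep), nzchar(sep))
  if (anyDuplicated(treatments)) {
    rlang::abort("duplicated treatment labels", class = "cnma_validation_error")
  }
  if (!is.null(inactive)) {
    if (!inactive %in% treatments) {
      rlang::abort(paste0("inactive treatment `", inactive, "` is not a treatment"),
                   class = "cnma_validation_error")
    }
    if (grepl(sep, inactive, fixed = TRUE)) {
      rlang::abort("the inactive treatment label must not contain the separator",
                   class = "cnma_validation_error")
    }
  }
  tokens <- lapply(treatments, function(tr) {
    tk <- trimws(strsplit(tr, sep, fixed = TRUE)[[1L]])
    if (any(!nzchar(tk)) || length(tk) == 0L) {
      rlang::abort(paste0("treatment `", tr, "` parses to an empty component"),
                   class = "cnma_validation_error")
    }
    tk
  })
  names(tokens) <- treatments
  if (!is.null(dose)) {
    stopifnot(is.list(dose), !is.null(names(dose)))
    if (!all(names(dose) %in% treatments)) {
      rlang::abort("dose coding refers to unknown treatments",
                   class = "cnma_validation_error")
    }
  }
  dose_comps <- unlist(lapply(dose, names))
  components <- sort(setdiff(
    unique(c(unlist(tokens[setdiff(treatments, names(dose))]), dose_comps)),
    inactive), method = "radix")
  C <- matrix(0, length(treatments), length(components),
              dimnames = list(treatments, components))
  for (tr in treatments) {
    if (!is.null(dose) && tr %in% names(dose)) {
      C[tr, names(dose[[tr]])] <- dose[[tr]]
    } else if (!identical(tr, inactive)) {
      C[tr, intersect(tokens[[tr]], components)] <- 1
    }
  }
  if (any(colSums(abs(C)) == 0)) {
    rlang::abort("component with all-zero column in C",
                 class = "cnma_validation_error")
  }
  structure(
    list(components = components, C = C, inactive = inactive, sep = sep),
    class = "component_structure"
  )
}

#' @export
print.component_structure <- function(x, ...) {
  cat("Component structure: ", nrow(x$C), " treatments x ",
      ncol(x$C), " components", sep = "")
  if (!is.null(x$inactive)) cat(" (inactive: ", x$inactive, ")", sep = "")
  cat("\n")
  print(x$C, ...)
  invisible(x)
}

#' Append interaction columns to a component structure
#'
#' Extends the combination matrix with one column per requested component
#' set; a treatment gets a 1 in the new column iff it contains every
#' component of the set. Interaction columns are labelled with the sorted
#' components joined by `*`. Requesting an interaction that occurs in no
#' treatment is an error (the column would be all zero, hence inestimable).
#'
#' @param comps a `component_structure`.
#' @param pairs interactions to add: a character vector of `"A*B"` labels or
#'   a list of character vectors of component names (sets of size >= 2).
#' @return a new `component_structure` with `c` incremented per interaction.
#' @examples
#' cs <- build_combination(c("A", "A+B", "A+B+C", "B+C", "placebo"),
#'                         inactive = "placebo")
#' add_interactions(cs, "A*B")$C
#' @export
add_interactions <- function(comps, pairs) {
  stopifnot(inherits(comps, "component_structure"))
  if (is.character(pairs)) pairs <- strsplit(pairs, "*", fixed = TRUE)
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  C <- comps$C
  base_components <- setdiff(colnames(C), grep("*", colnames(C), fixed = TRUE,
                                               value = TRUE))
  for (set in pairs) {
    set <- sort(trimws(as.character(set)), method = "radix")
    if (length(set) < 2L || anyDuplicated(set)) {
      rlang::abort("an interaction needs >= 2 distinct components",
                   class = "cnma_validation_error")
    }
    if (!all(set %in% base_components)) {
      rlang::abort(paste0("unknown component(s): ",
                          paste(setdiff(set, base_components), collapse = ", ")),
                   class = "cnma_validation_error")
    }
    label <- paste(set, collapse = "*")
    if (label %in% colnames(C)) {
      rlang::abort(paste0("interaction ", label, " already present"),
                   class = "cnma_validation_error")
    }
    col <- as.numeric(rowSums(C[, set, drop = FALSE] > 0) == length(set))
    if (sum(col) == 0) {
      rlang::abort(paste0("interaction ", label,
                          " occurs in no treatment (all-zero column)"),
                   class = "cnma_validation_error")
    }
    C <- cbind(C, col)
    colnames(C)[ncol(C)] <- label
  }
  out <- comps
  out$C <- C
  out$components <- colnames(C)
  out
}

# m x c additive design matrix Xa = B C, with comps aligned to the network's
# treatment order
build_design <- function(network, comps) {
  stopifnot(inherits(network, "nma_network"),
            inherits(comps, "component_structure"))
  if (!setequal(rownames(comps$C), network$treatments)) {
    rlang::abort("component structure does not cover the network's treatments",
                 class = "cnma_usage_error")
  }
  B <- build_incidence(network)
  B %*% comps$C[network$treatments, , drop = FALSE]
}
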