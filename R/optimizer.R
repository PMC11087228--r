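#' Candidate optimal strains from a significance report
#'
#' A strain is predicted optimal when every enzyme with a significant main
#' effect sits at the level matching the sign of its coefficient; enzymes
#' with insignificant main effects are left free, so the candidate set has
#' `2^(k - n_significant)` members.
#'
#' @param report A [significant_effects()] result.
#' @param factor_names The k factor labels (defines column order of the
#'   output).
#' @return An object of class `candidate_set`: list with `strains` (coded
#'   matrix) and `source` (the report).
#' @export
candidate_optima <- function(report, factor_names = PATHWAY_ENZYMES) {
  k <- length(factor_names)
  sig <- names(report$signs)
  if (!all(sig %in% factor_names)) {
    stop("report refers to factors outside factor_names")
  }
  free <- setdiff(factor_names, sig)
  if (length(free)) {
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(free))))
    colnames(grid) <- free
  } else {
    grid <- matrix(numeric(0), 1, 0)
  }
  m <- matrix(NA_real_, nrow(grid), k, dimnames = list(NULL, factor_names))
  for (f in sig) m[, f] <- report$signs[[f]]
  for (f in free) m[, f] <- grid[, f]
  structure(list(strains = m, source = report), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate optimal strains:", nrow(x$strains), "of 2^",
      ncol(x$strains), "\n", sep = "")
  invisible(x)
}

#' Strain selection frequency over repeats
#'
#' Counts, for every strain of the full factorial space, in how many repeats
#' it was part of the candidate set, and normalizes by the number of repeats.
#' A strain counts once per repeat regardless of the candidate-set size.
#'
#' @param candidate_sets List of [candidate_optima()] results (or coded
#'   matrices), one per repeat.
#' @param factor_names The k factor labels.
#' @return An object of class `frequency_table`: data.frame with `strain`
#'   (coded string over +/-), `count` and `frequency`, sorted by decreasing
#'   frequency; attribute `n_repeats`.
#' @export
selection_frequency <- function(candidate_sets,
                                factor_names = PATHWAY_ENZYMES) {
  stopifnot(length(candidate_sets) >= 1)
  counts <- new.env(parent = emptyenv())
  for (cs in candidate_sets) {
    m <- if (inherits(cs, "candidate_set")) cs$strains else as.matrix(cs)
    for (code in unique(strain_codes(m))) {
      counts[[code]] <- (if (is.null(counts[[code]])) 0L else counts[[code]]) + 1L
    }
  }
  codes <- ls(counts)
  n <- length(candidate_sets)
  out <- data.frame(strain = codes,
                    count = vapply(codes, function(cd) counts[[cd]], integer(1)))
  out$frequency <- out$count / n
  out <- out[order(-out$frequency, out$strain), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_repeats") <- n
  class(out) <- c("frequency_table", "data.frame")
  out
}

# All permutations of 1:k in a deterministic order (k! small here).
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (p in sub) {
      i <- i + 1L
      out[[i]] <- c(first, rest[p])
    }
  }
  out
}

#' Fraction of factor assignments excluding the optimal pair
#'
#' For every assignment of factors to design columns (a column permutation),
#' checks whether either member of the optimal strain pair occurs among the
#' design's runs, and returns the fraction of assignments in which neither
#' does. With `mode = "all"` all `k!` assignments are enumerated; with
#' `mode = "sampled"` a seeded uniform sample is used.
#'
#' @param design A `doe_design`.
#' @param optimal_pair Coded matrix with one strain per row (typically the
#'   two ground-truth optima).
#' @param mode `"all"` or `"sampled"`.
#' @param n_samples,seed Sample size and seed for `mode = "sampled"`.
#' @return Scalar fraction in `[0, 1]`.
#' @export
#' @examples
#' pair <- rbind(c(-1, 1, -1, -1, -1, 1, 1), c(1, 1, -1, -1, -1, 1, 1))
#' optimal_inclusion_fraction(catalog_design("IV"), pair)  # 0.6
optimal_inclusion_fraction <- function(design, optimal_pair,
                                       mode = c("all", "sampled"),
                                       n_samples = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  m <- design_matrix(design)
  k <- ncol(m)
  pair <- as.matrix(optimal_pair)
  stopifnot(ncol(pair) == k)
  run_set <- strain_codes(m)

  # factor i -> column perm[i]; strain s is in the permuted design iff the
  # row with column perm[i] equal to s[i] exists, i.e. the vector v with
  # v[perm[i]] = s[i] is a run of the parent design.
  excluded_under <- function(perm) {
    for (r in seq_len(nrow(pair))) {
      v <- numeric(k)
      v[perm] <- pair[r, ]
      if (strain_code(v) %in% run_set) return(FALSE)
    }
    TRUE
  }

  perms <- if (mode == "all") all_permutations(k) else
    with_seed(seed, replicate(n_samples, sample.int(k), simplify = FALSE))
  mean(vapply(perms, excluded_under, logical(1)))
}

#' Ground-truth optimal strains of a library
#'
#' The argmax set of the noiseless truth; strains within `tol_rel` of the
#' maximum count as tied. The default 1e-3 separates biologically
#' indistinguishable strains (the TAL-level pair differs by about 1e-4
#' relative, a residual of the initial substrate-release transient) from the
#' smallest real effect in the shipped model (about 4e-2 relative).
#'
#' @param library A [simulate_library()] result.
#' @param tol_rel Relative tie tolerance.
#' @return Coded matrix of the tied top strains.
#' @export
true_optima <- function(library, tol_rel = 1e-3) {
  top <- max(library$truth)
  library$strains[library$truth >= top * (1 - tol_rel), , drop = FALSE]
}
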