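#' @title Two-level designs
#' @name designs
#' @description Generation and manipulation of coded two-level designs: full
#'   factorials, regular fractions (with generator words, defining relation
#'   and resolution), 12-run Plackett-Burman screening designs, random subsets
#'   of the full factorial, column permutation and row removal. Designs are
#'   `doe_design` objects: a runs-by-factors matrix of -1/+1 codes plus
#'   provenance.
NULL

new_design <- function(matrix, factor_names, provenance) {
  matrix <- as.matrix(matrix)
  dimnames(matrix) <- list(NULL, factor_names)
  if (!all(matrix %in% c(-1, 1, 0))) stop("design entries must be coded levels")
  structure(list(matrix = matrix, factor_names = factor_names,
                 provenance = provenance, n = ncol(matrix)),
            class = "doe_design")
}

#' Extract the coded run matrix of a design
#' @param design A `doe_design`.
#' @return Numeric matrix, one column per factor.
#' @export
design_matrix <- function(design) {
  if (inherits(design, "doe_design")) design$matrix else as.matrix(design)
}

#' @export
print.doe_design <- function(x, ...) {
  cat("Design (", x$provenance$type, "): ", nrow(x$matrix), " runs x ",
      x$n, " factors\n", sep = "")
  if (!is.null(x$provenance$generators)) {
    cat("  generators:",
        paste(names(x$provenance$generators), "=",
              vapply(x$provenance$generators, paste, "", collapse = ""),
              collapse = ", "), "\n")
  }
  invisible(x)
}

default_factor_names <- function(k) {
  if (k == 7L) PATHWAY_ENZYMES else paste0("F", seq_len(k))
}

#' Full factorial design
#'
#' All level combinations of `k` factors in standard (Yates) order: the first
#' factor cycles fastest. Two coded levels (-1, +1) by default; `levels = 3`
#' gives the three-level factorial (-1, 0, +1), provided only for
#' experiment-counting, not for the two-level analysis pipeline.
#'
#' @param k Number of factors (1-16).
#' @param factor_names Optional factor labels.
#' @param levels Number of levels per factor (2 or 3).
#' @return A `doe_design` with `levels^k` runs.
#' @export
#' @examples
#' nrow(design_matrix(full_factorial(3)))  # 8
full_factorial <- function(k, factor_names = default_factor_names(k),
                           levels = 2L) {
  stopifnot(k >= 1, k <= 16, levels %in% c(2L, 3L))
  codes <- if (levels == 2L) c(-1, 1) else c(-1, 0, 1)
  m <- as.matrix(expand.grid(rep(list(codes), k)))
  new_design(m, factor_names, list(type = "full_factorial", k = k,
                                   levels = levels))
}

parse_word <- function(word) {
  # "ABC" or c("A","B","C") -> vector of base-letter indices
  if (length(word) == 1L && nchar(word) > 1L) word <- strsplit(word, "")[[1]]
  idx <- match(word, LETTERS)
  if (any(is.na(idx))) stop("generator words use base letters A, B, C, ...")
  idx
}

#' Regular two-level fractional factorial
#'
#' A `2^(k-p)` fraction: the first `k - p` factors form a full factorial
#' (base columns, letters A, B, ...); each remaining factor is generated as a
#' product of base columns given by its generator word. The defining relation
#' and resolution follow from the generators.
#'
#' @param k Total number of factors.
#' @param generators Named list/character vector mapping each generated factor
#'   (position `k-p+1` to `k`) to a word over the base letters, e.g.
#'   `c(E = "ABC", F = "ABD", G = "ACD")`.
#' @param factor_names Optional factor labels.
#' @return A `doe_design` with `2^(k - length(generators))` runs.
#' @export
#' @examples
#' d <- regular_fraction(7, c(E = "ABC", F = "ABD", G = "ACD"))
#' nrow(design_matrix(d))  # 16
regular_fraction <- function(k, generators,
                             factor_names = default_factor_names(k)) {
  p <- length(generators)
  stopifnot(p >= 1, p < k)
  words <- lapply(generators, parse_word)
  if (anyDuplicated(vapply(words, function(w) paste(sort(w), collapse = ""),
                           ""))) {
    stop("duplicate generator words")
  }
  base_k <- k - p
  if (any(unlist(words) > base_k)) {
    stop("generator words may only use the ", base_k, " base letters")
  }
  base <- design_matrix(full_factorial(base_k))
  gen_cols <- vapply(words, function(w) apply(base[, w, drop = FALSE], 1, prod),
                     numeric(nrow(base)))
  m <- cbind(base, gen_cols)
  new_design(m, factor_names,
             list(type = "regular_fraction", k = k, p = p,
                  generators = lapply(generators, function(w)
                    strsplit(w, "")[[1]])))
}

#' Shipped design catalog for seven factors
#'
#' The four fractional designs compared throughout the package, pinned to
#' fixed (minimum aberration) generators:
#' \describe{
#'   \item{"V"}{the 64-run half fraction with G = ABCDEF. Its defining word
#'     has length 7 (true resolution VII); it is the design returned when
#'     resolution at least V is requested for 7 factors, and is labelled
#'     "resolution V" accordingly.}
#'   \item{"IV"}{the 16-run 2^(7-3) with E = ABC, F = ABD, G = ACD.}
#'   \item{"III"}{the saturated 8-run 2^(7-4) with D = AB, E = AC, F = BC,
#'     G = ABC.}
#'   \item{"PB"}{the 12-run Plackett-Burman design.}
#' }
#'
#' @param which One of `"V"`, `"IV"`, `"III"`, `"PB"`.
#' @param factor_names Optional factor labels.
#' @return A `doe_design` with 7 factors.
#' @export
catalog_design <- function(which = c("V", "IV", "III", "PB"),
                           factor_names = PATHWAY_ENZYMES) {
  which <- match.arg(which)
  switch(which,
    V = regular_fraction(7, c(G = "ABCDEF"), factor_names),
    IV = regular_fraction(7, c(E = "ABC", F = "ABD", G = "ACD"), factor_names),
    III = regular_fraction(7, c(D = "AB", E = "AC", F = "BC", G = "ABC"),
                           factor_names),
    PB = plackett_burman(12, 7, factor_names))
}

#' Plackett-Burman design
#'
#' The 12-run Plackett-Burman screening design: the cyclic generator row
#' `+ + - + + + - - - + -` and its 10 cyclic shifts, with a final all-minus
#' run; the first `k` columns are used. Columns are pairwise orthogonal but
#' main effects are partially (+/- 1/3) correlated with two-factor
#' interactions.
#'
#' @param n_runs Number of runs; only 12 is supported.
#' @param k Number of factors (at most `n_runs - 1`).
#' @param factor_names Optional factor labels.
#' @return A `doe_design`.
#' @export
plackett_burman <- function(n_runs = 12L, k,
                            factor_names = default_factor_names(k)) {
  if (n_runs != 12L) stop("only the 12-run Plackett-Burman design is supported")
  stopifnot(k >= 1, k <= n_runs - 1)
  gen <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)
  m <- t(vapply(0:10, function(s) gen[(seq_len(11) - 1 + s) %% 11 + 1],
                numeric(11)))
  m <- rbind(m, rep(-1, 11))[, seq_len(k), drop = FALSE]
  new_design(m, factor_names, list(type = "plackett_burman", n_runs = n_runs,
                                   k = k))
}

#' Permute the factor-to-column assignment of a design
#'
#' Models the experimenter's arbitrary assignment of enzymes to design
#' columns: factor `i` is assigned the parent design's column
#' `permutation[i]`. Row order, run count and the design's geometric
#' structure (hence resolution) are unchanged; signs are never flipped.
#'
#' @param design A `doe_design`.
#' @param permutation Integer permutation of `1:k`.
#' @return A `doe_design` with provenance recording the parent and permutation.
#' @export
permute_columns <- function(design, permutation) {
  k <- design$n
  if (!identical(sort(as.integer(permutation)), seq_len(k))) {
    stop("permutation must be a permutation of 1:", k)
  }
  m <- design$matrix[, permutation, drop = FALSE]
  new_design(m, design$factor_names,
             list(type = "derived", parent = design$provenance,
                  permutation = as.integer(permutation)))
}

#' Remove random rows from a design
#'
#' Emulates strains that could not be constructed: `n_missing` rows are
#' removed uniformly at random without replacement.
#'
#' @param design A `doe_design`.
#' @param n_missing Number of rows to remove (less than the run count).
#' @param seed Integer seed.
#' @return A `doe_design`; surviving rows keep their original order.
#' @export
drop_rows <- function(design, n_missing, seed) {
  n <- nrow(design$matrix)
  if (n_missing < 0 || n_missing >= n) {
    stop("n_missing must be in [0, runs - 1]")
  }
  if (n_missing == 0) return(design)
  drop <- with_seed(seed, sample.int(n, n_missing))
  new_design(design$matrix[-drop, , drop = FALSE], design$factor_names,
             list(type = "derived", parent = design$provenance,
                  dropped_rows = sort(drop), seed = as.integer(seed)))
}

#' Random subset of the full factorial
#'
#' `n` distinct runs sampled uniformly without replacement from the `2^k`
#' full factorial — the random-construction baseline matched in size to each
#' fractional design.
#'
#' @param k Number of factors.
#' @param n Sample size (at most `2^k`).
#' @param seed Integer seed.
#' @param factor_names Optional factor labels.
#' @return A `doe_design` with `n` runs.
#' @export
random_subset <- function(k, n, seed, factor_names = default_factor_names(k)) {
  full <- design_matrix(full_factorial(k, factor_names))
  if (n > nrow(full)) stop("n must be at most 2^k = ", nrow(full))
  idx <- with_seed(seed, sort(sample.int(nrow(full), n)))
  new_design(full[idx, , drop = FALSE], factor_names,
             list(type = "random_subset", k = k, n = n, seed = as.integer(seed)))
}

# Strain row -> compact code like "+--++-+" (factor order of the design).
strain_code <- function(levels) {
  paste(ifelse(levels > 0, "+", "-"), collapse = "")
}

strain_codes <- function(matrix) apply(matrix, 1, strain_code)
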