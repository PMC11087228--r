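#' Effect-model terms of a design
#'
#' Deterministic term ordering used by the whole package: intercept, main
#' effects in factor order, then two-factor interactions in lexicographic
#' pair order (`1:2, 1:3, ..., (k-1):k`), named `"A:B"` with the factor
#' labels.
#' @keywords internal
effect_terms <- function(factor_names, include_2fi = TRUE) {
  k <- length(factor_names)
  terms <- c("(Intercept)", factor_names)
  if (include_2fi && k >= 2) {
    pairs <- utils::combn(k, 2)
    terms <- c(terms, paste(factor_names[pairs[1, ]],
                            factor_names[pairs[2, ]], sep = ":"))
  }
  terms
}

effect_columns <- function(m, include_2fi = TRUE) {
  k <- ncol(m)
  out <- cbind(`(Intercept)` = rep(1, nrow(m)), m)
  if (include_2fi && k >= 2) {
    pairs <- utils::combn(k, 2)
    fi <- m[, pairs[1, ], drop = FALSE] * m[, pairs[2, ], drop = FALSE]
    colnames(fi) <- paste(colnames(m)[pairs[1, ]],
                          colnames(m)[pairs[2, ]], sep = ":")
    out <- cbind(out, fi)
  }
  out
}

# Cosine similarity between model-matrix columns. For balanced +/-1 columns
# this coincides with the Pearson correlation and is additionally defined for
# the constant intercept column; |cosine| = 1 iff the columns are identical
# up to sign, the operational definition of aliasing.
column_cosine <- function(x) {
  nrm <- sqrt(colSums(x^2))
  crossprod(x) / tcrossprod(nrm)
}

#' Alias structure of a design
#'
#' Computes, by brute force on the intercept + main effect + two-factor
#' interaction model matrix, which terms are completely aliased (columns
#' identical up to sign) and the full matrix of partial correlations between
#' main-effect and interaction columns. For regular fractions the defining
#' relation is also derived from the generator words and the resolution is
#' its minimum word length; the two routes agree by construction and the
#' tests assert it.
#'
#' @param design A `doe_design`.
#' @param max_order Highest interaction order in the model matrix (only 2 is
#'   supported).
#' @return An object of class `alias_structure`: list with `alias_classes`
#'   (list of character vectors of term names; singletons are clear of
#'   confounding), `partial_correlations` (ME x 2FI cosine matrix),
#'   `defining_words` (character vector or NULL), `resolution` (integer or
#'   NA for non-regular designs).
#' @export
#' @examples
#' a <- alias_structure(catalog_design("IV"))
#' a$resolution
alias_structure <- function(design, max_order = 2L) {
  stopifnot(max_order == 2L)
  m <- design_matrix(design)
  mm <- effect_columns(m)
  cs <- column_cosine(mm)
  tol <- 1e-8
  terms <- colnames(mm)
  aliased <- abs(abs(cs) - 1) < tol

  # connected components of the "fully aliased" relation
  remaining <- seq_along(terms)
  classes <- list()
  while (length(remaining)) {
    i <- remaining[1]
    cls <- which(aliased[i, ])
    classes[[length(classes) + 1L]] <- terms[cls]
    remaining <- setdiff(remaining, cls)
  }

  k <- ncol(m)
  me <- terms[2:(k + 1)]
  fi <- terms[-seq_len(k + 1)]
  pc <- cs[me, fi, drop = FALSE]

  words <- defining_words(design)
  res <- if (is.null(words)) NA_integer_ else min(nchar(words))
  structure(list(alias_classes = classes, partial_correlations = pc,
                 defining_words = words, resolution = res),
            class = "alias_structure")
}

#' @export
print.alias_structure <- function(x, ...) {
  nontriv <- Filter(function(cl) length(cl) > 1, x$alias_classes)
  cat("Alias structure: resolution",
      if (is.na(x$resolution)) "partial (non-regular)" else
        as.character(as.roman(x$resolution)), "\n")
  if (length(nontriv)) {
    for (cl in nontriv) cat("  ", paste(cl, collapse = " = "), "\n")
  } else cat("  all intercept/ME/2FI terms clear of confounding\n")
  invisible(x)
}

# Defining relation of a regular fraction: every product of a non-empty
# subset of generator words (letters XOR). Returns words as strings over the
# design's base letters, NULL for non-regular designs.
defining_words <- function(design) {
  prov <- design$provenance
  if (!identical(prov$type, "regular_fraction")) return(NULL)
  k <- prov$k; p <- prov$p
  gen_words <- lapply(seq_len(p), function(i) {
    sort(c(match(prov$generators[[i]], LETTERS), k - p + i))
  })
  words <- character(0)
  for (subset in seq_len(2^p - 1)) {
    w <- integer(0)
    for (i in seq_len(p)) {
      if (bitwAnd(subset, bitwShiftL(1L, i - 1L))) {
        w <- union(setdiff(w, gen_words[[i]]), setdiff(gen_words[[i]], w))
      }
    }
    words <- c(words, paste(LETTERS[sort(w)], collapse = ""))
  }
  sort(words)
}
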