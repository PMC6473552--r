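# Parsimonious reformulation of the analysis model for the confirmatory
# trial. Once hypothesis selection restricts enrollment to particular
# biomarker-treatment combinations, some full-model parameters have
# identically-zero design columns (never observed) and others are
# confounded on the support; the former are dropped and the latter folded
# into combined parameters that record which full-model linear combination
# they estimate, so that true effect sizes remain computable in full-model
# coordinates.

#' Design points enrolled by a set of hypotheses
#'
#' Each treatment-versus-control hypothesis enrolls two design points: its
#' subgroup (the biomarker profile positive exactly for the biomarkers whose
#' interactions enter the contrast) under control, and under the tested
#' treatment.
#'
#' @param contrasts List of [contrast()] objects in full-model coordinates.
#' @inheritParams full_term_labels
#' @return Subset of [enumerate_support()] rows (original indices kept).
#' @export
hypothesis_support <- function(contrasts, K, L) {
  sup <- enumerate_support(K, L)
  keep <- logical(nrow(sup))
  for (con in contrasts) {
    cf <- con$coef[con$coef != 0]
    k <- grep("^beta[0-9]$", names(cf), value = TRUE)
    stopifnot(length(k) == 1L)
    k <- as.integer(sub("beta", "", k))
    S <- as.integer(sub(sprintf("delta%d", k), "",
                        grep(sprintf("^delta%d[0-9]$", k), names(cf),
                             value = TRUE)))
    x <- as.integer(seq_len(L) %in% S)
    prof_match <- rep(TRUE, nrow(sup))
    for (l in seq_len(L)) {
      prof_match <- prof_match & sup[[paste0("x", l)]] == x[l]
    }
    keep <- keep | (prof_match & sup$arm %in% c(0L, k))
  }
  sup[keep, , drop = FALSE]
}

# name for a group of perfectly confounded parameters: a treatment main
# effect plus its interactions keeps the field's "primed" convention
merged_name <- function(labels) {
  bk <- grep("^beta", labels, value = TRUE)
  if (length(bk) == 1L) paste0(bk, "p") else paste(labels, collapse = ".")
}

#' Reduce the analysis model to the terms estimable on a support
#'
#' Given selected hypotheses and the design points that will be enrolled,
#' produces a reparameterized analysis model whose information matrix is
#' full rank on that support: parameters with identically-zero design
#' columns are dropped, perfectly coinciding columns are merged into single
#' combined parameters (e.g. `beta2p = beta2 + delta22` when treatment 2 is
#' only given to biomarker-2-positive patients), and any remaining linear
#' dependence is folded into the retained parameters with exact substitution
#' records. The selected contrasts are re-expressed in the reduced
#' coordinates; an error is raised if a selected contrast is not estimable
#' on the support.
#'
#' @param selected List of [contrast()] objects (full-model coordinates).
#' @param spec Full-model [regression_spec()].
#' @param support Data frame of enrolled design points; default
#'   [hypothesis_support()] of the selection.
#' @return List of class `reduced_model` with elements `spec` (reduced
#'   [regression_spec()]), `contrasts` (selection in reduced coordinates),
#'   `support`, and `dropped` (labels removed).
#' @export
#' @examples
#' cat22 <- contrast_catalogue(2, 2)
#' reduce_model(cat22[c(1, 2, 7, 8)], regression_spec(2, 2))
reduce_model <- function(selected, spec, support = NULL) {
  stopifnot(is_full_spec(spec), length(selected) >= 1)
  if (is.null(support)) support <- hypothesis_support(selected, spec$K, spec$L)
  F <- design_rows(support, spec)
  full <- colnames(F)
  nonzero <- colSums(abs(F)) > 0
  dropped <- full[!nonzero]

  # working terms: name, full-model combination, design column on support;
  # the first element of each combination is the retained column's label
  terms <- lapply(full[nonzero], function(lab) {
    list(name = lab, combo = setNames(1, lab), col = F[, lab])
  })

  # merge perfectly coinciding columns
  key <- vapply(terms, function(tm) paste(tm$col, collapse = "/"),
                character(1))
  terms <- lapply(split(terms, factor(key, levels = unique(key))), function(g) {
    if (length(g) == 1L) return(g[[1L]])
    labs <- vapply(g, `[[`, character(1), "name")
    list(name = merged_name(labs),
         combo = setNames(rep(1, length(labs)), labs),
         col = g[[1L]]$col)
  })
  terms <- terms[order(match(vapply(terms, function(tm) names(tm$combo)[1],
                                    character(1)), full))]

  # fold remaining linear dependence (pivoted QR) into the kept terms
  Fm <- do.call(cbind, lapply(terms, `[[`, "col"))
  qf <- qr(Fm)
  if (qf$rank < ncol(Fm)) {
    keep <- sort(qf$pivot[seq_len(qf$rank)])
    dep <- sort(qf$pivot[-seq_len(qf$rank)])
    coefs <- qr.coef(qr(Fm[, keep, drop = FALSE]),
                     Fm[, dep, drop = FALSE])
    coefs[is.na(coefs)] <- 0
    coefs <- zapsmall(coefs, digits = 10)
    kept <- terms[keep]
    for (j in seq_along(keep)) {
      for (d in seq_along(dep)) {
        if (coefs[j, d] != 0) {
          add <- coefs[j, d] * terms[[dep[d]]]$combo
          cmb <- kept[[j]]$combo
          for (lab in names(add)) {
            cmb[lab] <- (if (lab %in% names(cmb)) cmb[[lab]] else 0) +
              add[[lab]]
          }
          kept[[j]]$combo <- cmb[cmb != 0]
        }
      }
      if (length(kept[[j]]$combo) > 1L && kept[[j]]$name %in% full) {
        kept[[j]]$name <- paste0(kept[[j]]$name, "p")
      }
    }
    terms <- kept
  }
  nms <- make.unique(vapply(terms, `[[`, character(1), "name"), sep = "_")
  unit <- mapply(function(tm, nm) {
    identical(tm$combo, setNames(1, nm))
  }, terms, nms)
  substitutions <- setNames(lapply(terms[!unit], `[[`, "combo"), nms[!unit])

  red <- regression_spec(spec$K, spec$L, terms = nms,
                         substitutions = substitutions,
                         support = support$i)
  Fr <- design_rows(support, red)
  if (qr(Fr)$rank < ncol(Fr)) {
    stop("internal error: reduced model is still rank deficient")
  }

  # re-express each selected contrast: find c_red with map %*% c_red = c_full
  qa <- qr(red$map)
  contrasts <- lapply(selected, function(con) {
    cf <- setNames(numeric(nrow(red$map)), rownames(red$map))
    cf[names(con$coef)] <- con$coef
    cr <- qr.coef(qa, cf)
    cr[is.na(cr)] <- 0
    if (max(abs(red$map %*% cr - cf)) > 1e-8) {
      stop("selected contrast ", if (!is.na(con$r)) paste0("r=", con$r),
           " (", con$label, ") is not estimable on the given support")
    }
    contrast(setNames(round(cr, 12), colnames(red$map)),
             tau = con$tau, r = con$r, label = con$label)
  })
  structure(list(spec = red, contrasts = contrasts, support = support,
                 dropped = dropped),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("parsimonious analysis model\n")
  print(x$spec)
  if (length(x$dropped)) {
    cat("  dropped (never observed):", paste(x$dropped, collapse = ", "), "\n")
  }
  cat(sprintf("  %d selected hypotheses on %d design points\n",
              length(x$contrasts), nrow(x$support)))
  invisible(x)
}
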