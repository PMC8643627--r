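#' Reverse complement of a motif matrix
#'
#' Reverses the column order and swaps A with T and C with G.
#'
#' @param profile a 4 x width probability matrix with rows A, C, G, T.
#' @return the reverse-complemented matrix.
#' @export
revCompProfile <- function(profile) {
  out <- profile[c("T", "G", "C", "A"), rev(seq_len(ncol(profile))),
                 drop = FALSE]
  rownames(out) <- DNA_BASES4
  out
}

#' Build a nuclear-receptor repeat variant from a half-site
#'
#' Assembles direct (DR), inverted (IR, head-to-head) and everted (ER,
#' tail-to-tail) repeats of a half-site matrix `H` with a
#' background-uniform spacer `S` of 0-8 bp:
#' `DR = H S H`, `IR = H S revcomp(H)`, `ER = revcomp(H) S H`
#' (standard nuclear-receptor response-element nomenclature). The variant
#' is named `<orientation><spacing>`, e.g. `DR5`.
#'
#' @param halfSite a [MotifMatrix-class] half-site.
#' @param orientation one of `"DR"`, `"IR"`, `"ER"`.
#' @param spacing spacer width in bp, 0-8.
#' @return a [CompositeMotif-class].
#' @examples
#' buildComposite(rarHalfSite(), "DR", 5)
#' @export
buildComposite <- function(halfSite, orientation = c("DR", "IR", "ER"),
                           spacing = 0L) {
  orientation <- match.arg(orientation)
  spacing <- as.integer(spacing)
  if (spacing < 0L || spacing > 8L) stop("spacing must be in 0..8")
  H <- motifProfile(halfSite)
  S <- matrix(0.25, 4L, spacing, dimnames = list(DNA_BASES4, NULL))
  prof <- switch(orientation,
    DR = cbind(H, S, H),
    IR = cbind(H, S, revCompProfile(H)),
    ER = cbind(revCompProfile(H), S, H))
  colnames(prof) <- NULL
  new("CompositeMotif",
      MotifMatrix(sprintf("%s%d", orientation, spacing), prof,
                  clusterId = sprintf("%s%d", orientation, spacing),
                  background = motifBackground(halfSite)),
      orientation = orientation, spacing = spacing, halfSite = H)
}

#' All repeat variants over orientations and spacings
#'
#' @param halfSite a [MotifMatrix-class] half-site.
#' @param orientations subset of DR/IR/ER (default all three).
#' @param spacings spacer widths (default 0:8), giving the full 27-variant
#'   panel.
#' @return named list of [CompositeMotif-class] objects.
#' @export
buildAllComposites <- function(halfSite, orientations = c("DR", "IR", "ER"),
                               spacings = 0:8) {
  out <- list()
  for (o in orientations)
    for (s in spacings)
      out[[sprintf("%s%d", o, s)]] <- buildComposite(halfSite, o, s)
  out
}

#' Consensus RAR/RXR half-site matrix
#'
#' The hexameric nuclear-receptor consensus half-site RGKTCA
#' (R = A/G, K = G/T) rendered as a probability matrix: degenerate
#' positions split 0.455/0.455 between their two bases, determinate
#' positions put 0.91 on the consensus base, 0.03 elsewhere. This is a
#' consensus-derived synthetic matrix, the half-site from which the
#' DR/IR/ER spacing variants are assembled.
#'
#' @param background background base frequencies.
#' @return a [MotifMatrix-class] of width 6.
#' @export
rarHalfSite <- function(background = rep(0.25, 4)) {
  cols <- list(
    R = c(A = 0.455, C = 0.045, G = 0.455, T = 0.045),
    G = c(A = 0.03, C = 0.03, G = 0.91, T = 0.03),
    K = c(A = 0.045, C = 0.045, G = 0.455, T = 0.455),
    T = c(A = 0.03, C = 0.03, G = 0.03, T = 0.91),
    C = c(A = 0.03, C = 0.91, G = 0.03, T = 0.03),
    A = c(A = 0.91, C = 0.03, G = 0.03, T = 0.03))
  prof <- do.call(cbind, lapply(cols, function(x) x[DNA_BASES4]))
  dimnames(prof) <- list(DNA_BASES4, NULL)
  MotifMatrix("RGKTCA_halfsite", prof, clusterId = "RAR_halfsite",
              background = background)
}
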