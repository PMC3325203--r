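#' Expected autozygous tract length under Haldane's recombination model
#'
#' An IBD segment inherited intact from a common ancestor \code{g}
#' generations back has exponential length with mean \code{1/(2g)} Morgans.
#'
#' @param g generations since the common ancestor (>= 1)
#' @return expected tract length in Morgans
#' @export
haldaneMeanLength <- function(g) {
  if (any(g < 1)) stop("g must be >= 1")
  1 / (2 * g)
}

#' Infer generation depth from observed tract lengths
#'
#' Maximum-likelihood inversion of the exponential tract-length law:
#' \code{g_hat = 1 / (2 * mean(lengths))}.
#'
#' @param lengths_morgans observed tract lengths in Morgans
#' @return estimated generations to the common ancestor
#' @export
inferGenerations <- function(lengths_morgans) {
  if (!length(lengths_morgans)) stop("no tract lengths supplied")
  if (any(lengths_morgans <= 0)) stop("tract lengths must be positive")
  1 / (2 * mean(lengths_morgans))
}
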