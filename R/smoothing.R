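# Post-hoc temporal smoothing of labels. The clustering annotates each
# location independently of its temporal context; isolated one-point label
# switches ("singles") can be relabelled to match their neighbours when the
# posterior-weight margin for the current label is small.

#' Find singles in a label sequence
#'
#' A single is an interior location whose label differs from the common label
#' of both its neighbours.
#'
#' @param labels vector of labels (length >= 3).
#' @return integer indices of singles (between 2 and n - 1).
#' @export
find_singles <- function(labels) {
  n <- length(labels)
  if (n < 3L) stop("need at least 3 labels")
  i <- 2:(n - 1L)
  i[labels[i - 1L] == labels[i + 1L] & labels[i] != labels[i - 1L]]
}

#' Smooth single-point label switches
#'
#' Relabels each single to its neighbours' label when the posterior-weight
#' margin of the change is acceptable: w_current - w_neighbour <= delta_w,
#' where the weights are the point's posteriors for its current cluster and
#' the neighbours' cluster. delta_w in [0, 1] expresses the willingness to
#' accept the change (0 only accepts switches the posteriors are indifferent
#' about; 1 accepts all). Within a pass the condition is evaluated on the
#' original labels and changes are applied afterwards, so the result does not
#' depend on scan order; singles are re-detected between passes.
#'
#' @param labels character or factor label sequence; values must match
#'   columns of \code{W}.
#' @param W n x k matrix of posterior weights with column names matching the
#'   label values (rows of invalid points may be \code{NA}: they are never
#'   relabelled and never block their neighbours).
#' @param delta_w margin threshold in [0, 1].
#' @param passes number of smoothing passes.
#' @return relabelled vector of the same type as \code{labels}.
#' @export
smooth_labels <- function(labels, W, delta_w = 0, passes = 1L) {
  stopifnot(delta_w >= 0, delta_w <= 1, passes >= 1)
  lab <- as.character(labels)
  if (is.null(colnames(W))) stop("W must have column names matching labels")
  for (p in seq_len(passes)) {
    singles <- find_singles(lab)
    if (!length(singles)) break
    newlab <- lab
    for (i in singles) {
      cur <- lab[i]
      nb <- lab[i - 1L]
      w_ic <- W[i, cur]
      w_in <- W[i, nb]
      if (is.na(w_ic) || is.na(w_in)) next
      if (w_ic - w_in <= delta_w) newlab[i] <- nb
    }
    if (identical(newlab, lab)) break
    lab <- newlab
  }
  if (is.factor(labels)) factor(lab, levels = levels(labels)) else lab
}
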