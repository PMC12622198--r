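# Affinity head, confidence (binned lDDT) pathway, free-energy conversion,
# endpoint aggregation and the regression metric stack.

affinity_endpoints <- c("pIC50", "pKi", "pKd", "pEC50")

#' Four-endpoint affinity head
#'
#' Pools decoder features into the affinity prediction:
#' ligand atoms are gated (invariant/equivariant fusion) and pooled twice,
#' once scaled by the constant C = 100 and once by the atom count |L|; pocket
#' atoms are gated and mean-pooled; ligand-pocket edge features are averaged
#' over valid pairs (binary mask weights). The concatenated descriptor is
#' mapped through an MLP with a ReLU output, so all four endpoint values
#' (pIC50, pKi, pKd, pEC50, log units) are nonnegative.
#'
#' @param p Parameter list.
#' @param lig_feat List with `h` (N x d) and `v` (equivariant list) from the
#'   decoder.
#' @param pocket_feat List with `h`, `v` from the pocket encoder.
#' @param cross_edges (N*M) x d_edge ligand-pocket edge features.
#' @param cfg [backbone_config()].
#' @param lig_mask,pocket_mask Optional logical validity masks.
#' @return A 1 x 4 matrix (or tape node) of endpoint values, columns ordered
#'   pIC50, pKi, pKd, pEC50.
#' @export
affinity_forward <- function(p, lig_feat, pocket_feat, cross_edges, cfg,
                             lig_mask = NULL, pocket_mask = NULL) {
  n <- nrow(vof(lig_feat$h)); m <- nrow(vof(pocket_feat$h))
  if (is.null(lig_mask)) lig_mask <- rep(TRUE, n)
  if (is.null(pocket_mask)) pocket_mask <- rep(TRUE, m)
  nl <- sum(lig_mask); np <- sum(pocket_mask)
  if (nl == 0L) stop("empty ligand: no valid atoms to pool")

  flig <- gated_fuse(lig_feat$h, lig_feat$v, p, "aff.gate_lig", "aff.Wgv.lig", lig_mask)
  fsum <- ad_csum(flig)
  zlig <- mlp2(ad_cbind(ad_scale(fsum, 1 / 100), ad_scale(fsum, 1 / nl)), p, "aff.zlig")

  fpocket <- gated_fuse(pocket_feat$h, pocket_feat$v, p, "aff.gate_pocket",
                        "aff.Wgv.pocket", pocket_mask)
  zpocket <- mlp2(ad_scale(ad_csum(fpocket), 1 / np), p, "aff.zpocket")

  w <- as.numeric(lig_mask[pair_i(n, m)] & pocket_mask[pair_j(n, m)])
  zint <- mlp2(ad_scale(ad_csum(ad_scale(cross_edges, w)), 1 / sum(w)), p, "aff.zint")

  ad_relu(mlp2(ad_cbind(zlig, zpocket, zint), p, "aff.out"))
}

#' Mean Huber loss over labeled affinity endpoints
#'
#' Quadratic for residuals up to `delta`, linear beyond; averaged over all
#' (sample, endpoint) entries that carry a label. With no labeled entries the
#' loss is defined as 0 and flagged with a warning.
#'
#' @param pred Numeric vector/matrix of predictions (samples x endpoints), or
#'   a single named vector.
#' @param target A named numeric vector, or a list of named vectors (one per
#'   sample); names select the labeled endpoints.
#' @param delta Huber transition point (log units), default 1.
#' @return Scalar loss; attribute `n_valid` carries the entry count.
#' @export
huber_affinity_loss <- function(pred, target, delta = 1) {
  if (!is.list(target)) target <- list(target)
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L,
                                         dimnames = list(NULL, names(pred) %||% affinity_endpoints))
  if (is.null(colnames(pred))) colnames(pred) <- affinity_endpoints
  errs <- numeric(0)
  for (i in seq_along(target)) {
    tt <- target[[i]]
    ep <- intersect(names(tt), colnames(pred))
    errs <- c(errs, pred[i, ep] - tt[ep])
  }
  if (!length(errs)) {
    warning("no labeled affinity endpoints; Huber loss defined as 0")
    return(structure(0, n_valid = 0L))
  }
  a <- abs(errs)
  h <- ifelse(a <= delta, 0.5 * errs^2, delta * (a - delta / 2))
  structure(mean(h), n_valid = length(errs))
}

# taped masked Huber for training: pred is a 1 x 4 node, target a named vector
ad_huber_masked <- function(pred, target, delta = 1) {
  pv <- vof(pred)
  mask <- as.numeric(affinity_endpoints %in% names(target))
  if (sum(mask) == 0) return(0)
  tvec <- rep(0, 4L)
  tvec[match(names(target), affinity_endpoints)] <- target
  e <- as.numeric(pv) - tvec
  a <- abs(e)
  val <- sum(ifelse(a <= delta, 0.5 * e^2, delta * (a - delta / 2)) * mask) / sum(mask)
  ad_result(val, list(pred), function(g)
    list(matrix(g * pmax(pmin(e, delta), -delta) * mask / sum(mask), 1L)))
}

#' Per-atom lDDT of a predicted ligand pose
#'
#' For each ligand atom, the fraction of its true ligand-pocket distances
#' below the 12 Angstrom inclusion radius (strict inequality) that are
#' preserved within the error thresholds: with L1 errors `L = |D - Dhat|`,
#' the score is `(1/b_i) sum_j (1/|tau|) sum_c [L_ij < c]`, with the neighbor
#' count `b_i` clamped to at least 1 (atoms with no neighbor score 0).
#'
#' @param d_true,d_pred Nonnegative |L| x |P| distance matrices (true and
#'   predicted ligand-pocket distances).
#' @param config An [lddt_config()].
#' @return Numeric vector of per-atom scores in \[0, 1\].
#' @export
lddt_per_atom <- function(d_true, d_pred, config = lddt_config()) {
  if (!identical(dim(d_true), dim(d_pred))) stop("distance matrix shapes differ")
  nbr <- d_true < config$inclusion_radius
  b <- pmax(rowSums(nbr), 1)
  L <- abs(d_true - d_pred)
  hits <- matrix(0, nrow(L), ncol(L))
  for (cthr in config$thresholds) hits <- hits + (L < cthr)
  rowSums(hits * nbr / length(config$thresholds)) / b
}

#' lDDT configuration
#'
#' @param inclusion_radius Neighbor inclusion radius (12 Angstrom; strict).
#' @param thresholds Error thresholds in Angstrom. Default 0.5/1/2/4, the
#'   universal lDDT convention; `printed_variant = TRUE` switches to 12/1/2/4.
#' @param k Number of confidence bins.
#' @param printed_variant Use the 12/1/2/4 threshold set.
#' @return An object of class `lddt_config`.
#' @export
lddt_config <- function(inclusion_radius = 12, thresholds = c(0.5, 1, 2, 4),
                        k = 50L, printed_variant = FALSE) {
  if (printed_variant) thresholds <- c(12, 1, 2, 4)
  thresholds <- sort(thresholds)
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  structure(list(inclusion_radius = inclusion_radius, thresholds = thresholds,
                 k = as.integer(k)), class = "lddt_config")
}

#' Bin an lDDT score into one of k classes
#'
#' `floor(score * k)` with score 1 mapped to the top bin `k - 1`; indices are
#' 0-based.
#'
#' @param score Scores in \[0, 1\].
#' @param k Bin count (default 50).
#' @return Integer bin indices in `0 .. k-1`.
#' @export
lddt_bin <- function(score, k = 50L) {
  if (any(score < 0 | score > 1)) stop("lDDT scores must lie in [0, 1]")
  pmin(floor(score * k), k - 1L)
}

#' Cross-entropy confidence loss against binned lDDT targets
#'
#' @param logits N x k logit matrix (plain or tape node).
#' @param true_lddt Per-atom lDDT scores in \[0, 1\].
#' @param k Bin count.
#' @return Mean cross-entropy (scalar or tape node).
#' @export
confidence_loss <- function(logits, true_lddt, k = ncol(vof(logits))) {
  n <- nrow(vof(logits))
  stopifnot(length(true_lddt) == n)
  bins <- lddt_bin(true_lddt, k) + 1L
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), bins)] <- 1
  ad_scale(ad_sum(ad_mul(ad_logsoftmax_rows(logits), onehot)), -1 / n)
}

# scalar pLDDT summary: 100 * mean expected bin center under the predicted
# per-atom bin distribution (bin center (i + 0.5) / k)
plddt_from_logits <- function(logits, k = ncol(logits)) {
  pm <- exp(logits - apply(logits, 1L, max))
  pm <- pm / rowSums(pm)
  centers <- (seq_len(k) - 0.5) / k
  per_atom <- as.numeric(pm %*% centers)
  list(per_atom = per_atom, plddt = 100 * mean(per_atom))
}

#' Convert a log-unit affinity to a binding free energy
#'
#' `dG = -R T ln(10) pK` with the gas constant R = 1.987e-3 kcal/(K mol) and
#' T = 298 K.
#'
#' @param pk Log-unit affinity (pIC50/pKi/pKd/pEC50), nonnegative.
#' @return Free energy in kcal/mol (nonpositive).
#' @export
delta_g_from_pk <- function(pk) {
  -(1.987e-3) * 298 * log(10) * pk
}

#' Aggregate endpoint predictions into one potency value
#'
#' @param pred Named numeric vector of endpoint values (any subset of pIC50,
#'   pKi, pKd, pEC50).
#' @param mode `"median"` (default) or `"mean"`.
#' @param mask Optional logical of the same length selecting valid endpoints.
#' @return Scalar aggregate.
#' @export
aggregate_endpoints <- function(pred, mode = c("median", "mean"), mask = NULL) {
  mode <- match.arg(mode)
  v <- as.numeric(pred)
  if (!is.null(mask)) v <- v[mask]
  if (!length(v)) stop("all endpoints masked")
  if (mode == "median") stats::median(v) else mean(v)
}

#' Regression metric stack
#'
#' RAE (relative absolute error against the mean predictor,
#' `sum|pred - true| / sum|true - mean(true)|`), RMSE, coefficient of
#' determination, Kendall tau-b and Pearson correlation.
#'
#' @param pred,true Numeric vectors of equal length >= 2.
#' @return Named list with `RAE`, `RMSE`, `R2`, `kendall_tau`, `pearson`.
#' @export
regression_metrics <- function(pred, true) {
  stopifnot(length(pred) == length(true), length(true) >= 2L,
            all(is.finite(pred)), all(is.finite(true)))
  if (stats::sd(true) == 0) stop("zero variance in true values: R2/Pearson undefined")
  err <- pred - true
  list(RAE = sum(abs(err)) / sum(abs(true - mean(true))),
       RMSE = sqrt(mean(err^2)),
       R2 = 1 - sum(err^2) / sum((true - mean(true))^2),
       kendall_tau = stats::cor(pred, true, method = "kendall"),
       pearson = stats::cor(pred, true, method = "pearson"))
}

#' Predict affinity and confidence for a ligand in a pocket
#'
#' Runs the decoder on the clean ligand at flow time 1 and reads the affinity
#' head and the confidence head.
#'
#' @param model A trained `pf_model`.
#' @param ligand A [ligand_state()] (clean pose, pocket-centroid frame).
#' @param pocket The [pocket_state()] context.
#' @return List with `affinity` (named vector of 4 endpoints), `aggregate`
#'   (median), `plddt` (scalar in \[0, 100\]) and `per_atom_lddt` (expected
#'   per-atom scores).
#' @export
predict_affinity <- function(model, ligand, pocket) {
  cfg <- model$config; p <- model$params
  penc <- pocket_encode(p, pocket, cfg)
  dec <- ligand_decode(p, ligand_drop_padding(ligand), 1, penc, cfg)
  y <- affinity_forward(p, dec$feat, penc, dec$feat$cross_edges, cfg)
  aff <- stats::setNames(as.numeric(y), affinity_endpoints)
  pl <- plddt_from_logits(vof(dec$conf_logits))
  list(affinity = aff, aggregate = aggregate_endpoints(aff),
       plddt = pl$plddt, per_atom_lddt = pl$per_atom)
}
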