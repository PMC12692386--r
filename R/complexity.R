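# Molecular complexity descriptors and indices. The Wiener and Bertz
# values follow the benchmark's printed formulas: WI is half the sum of
# all pairwise shortest-path distances on the heavy-atom graph, and BI is
# the per-atom sum of ln(degree!) - a simplified degree-entropy form,
# deliberately distinct from the classical Bertz CT.

#' Wiener index
#'
#' `WI = (1/2) * sum_ij d_ij` over all heavy-atom pairs, with `d_ij` the
#' shortest-path distance in bonds. Single atoms score 0; disconnected
#' molecules raise an error (infinite distances).
#'
#' @param record a valid `molecule_record` (or an internal graph).
#' @return non-negative number.
#' @examples
#' wiener_index(parse_and_sanitize("CCC")) # 4
#' @export
wiener_index <- function(record) {
  mol <- if (inherits(record, "molecule_record")) {
    if (!isTRUE(record$valid)) stop("invalid molecule record")
    record$mol
  } else record
  n <- n_atoms(mol)
  if (n <= 1L) return(0)
  adj <- adjacency(mol)
  total <- 0
  for (i in seq_len(n)) {
    d <- bfs_dist(adj, i, n)
    if (any(is.infinite(d))) stop("disconnected-graph: Wiener index undefined")
    total <- total + sum(d)
  }
  total / 2
}

#' Bertz index (degree-factorial form)
#'
#' `BI = sum_i ln(deg(i)!)` over heavy atoms, with `deg` the heavy-atom
#' bond count and the natural logarithm. This is the simplified printed
#' form used throughout the benchmark, not the classical Bertz CT.
#'
#' @param record a valid `molecule_record` (or an internal graph).
#' @return non-negative number.
#' @examples
#' bertz_index_degree(parse_and_sanitize("CCC")) # ln(2) for degrees 1,2,1
#' @export
bertz_index_degree <- function(record) {
  mol <- if (inherits(record, "molecule_record")) {
    if (!isTRUE(record$valid)) stop("invalid molecule record")
    record$mol
  } else record
  deg <- heavy_degree(mol)
  sum(lfactorial(deg))
}

#' Physicochemical complexity index
#'
#' `PCI = w_logP * logP + w_hb * (NHA - NHD)`: a composite of
#' lipophilicity and net hydrogen-bond-acceptor excess. Default weights
#' are (1, 1).
#'
#' @param record a valid `molecule_record`.
#' @param w_logp,w_hb weights for the two terms.
#' @param ob optional precomputed logP/TPSA row (batching).
#' @return numeric score.
#' @export
pci <- function(record, w_logp = 1, w_hb = 1, ob = NULL) {
  stopifnot(inherits(record, "molecule_record"), isTRUE(record$valid))
  if (is.null(ob)) ob <- ob_properties(record$smiles_canonical)
  hb <- hbond_counts(record$mol)
  w_logp * ob$logP[1] + w_hb * (hb[["NHA"]] - hb[["NHD"]])
}

# Hann simple-complexity proxy: structural feature density per heavy atom.
# The literature index it stands in for is not precisely specified, so the
# package uses (rings + heteroatoms + chiral centers) / heavy atoms and
# documents it as swappable.
hann_index <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(0)
  (ring_count(mol) + n_heteroatoms(mol) + sum(chiral_carbon_flags(mol))) / n
}

# ---- QED ------------------------------------------------------------------
# Quantitative estimate of drug-likeness: weighted geometric mean of
# asymmetric-double-sigmoid desirabilities over eight properties
# (Bickerton et al. parameterization). Structural-alert matching is not
# implemented; the alert count enters as zero for every molecule, which
# shifts QED by a molecule-independent factor within (0,1).
.QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000091, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140)
)
.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.qed_ads <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]; dmax <- p[7]
  v <- a + b / (1 + exp(-(x - cc + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - cc - d / 2) / f)))
  v / dmax
}

# count of fully aromatic perceived rings
n_aromatic_rings <- function(mol) {
  rings <- find_rings(mol, max_size = 7L)
  if (!length(rings)) return(0L)
  sum(vapply(rings, function(r) all(mol$atoms$aromatic[r]), TRUE))
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted-geometric-mean desirability over molecular weight, logP,
#' H-bond acceptors/donors, polar surface area, rotatable bonds, aromatic
#' rings and structural alerts (the alert count is zero in this
#' implementation). Values lie strictly inside (0, 1).
#'
#' @param record a valid `molecule_record`.
#' @param ob optional precomputed logP/TPSA row (batching).
#' @return QED score in (0, 1).
#' @export
qed <- function(record, ob = NULL) {
  stopifnot(inherits(record, "molecule_record"), isTRUE(record$valid))
  mol <- record$mol
  if (is.null(ob)) ob <- ob_properties(record$smiles_canonical)
  hb <- hbond_counts(mol)
  props <- c(MW = mol_weight(mol), ALOGP = ob$logP[1],
             HBA = unname(hb["NHA"]), HBD = unname(hb["NHD"]),
             PSA = ob$TPSA[1], ROTB = n_rotatable_bonds(mol),
             AROM = n_aromatic_rings(mol), ALERTS = 0)
  d <- vapply(names(props), function(k) .qed_ads(props[[k]], .QED_ADS[[k]]), 0)
  d <- pmin(pmax(d, 1e-12), 1)
  exp(sum(.QED_WEIGHTS * log(d)) / sum(.QED_WEIGHTS))
}

.COMPLEXITY_FIELDS <- c("MW", "NR", "NH", "QCF", "HCF",
                        "BI", "HI", "WI", "QED", "PCI")

#' Complexity profile of a molecule
#'
#' The ten complexity quantities tracked by the benchmark: molecular
#' weight (MW), ring count (NR), heteroatom count (NH), fraction of chiral
#' carbons (QCF, potential stereocenters over carbons), fraction of sp3
#' carbons (HCF), degree-factorial Bertz index (BI), Hann feature-density
#' proxy (HI), Wiener index (WI; `NA` for disconnected molecules), QED and
#' the physicochemical complexity index (PCI).
#'
#' @param record a valid `molecule_record`.
#' @param ob optional precomputed logP/TPSA row (batching).
#' @return named numeric vector with the ten fields.
#' @examples
#' complexity_profile(parse_and_sanitize("CCO"))[c("HCF", "NH", "NR")]
#' @export
complexity_profile <- function(record, ob = NULL) {
  stopifnot(inherits(record, "molecule_record"))
  if (!isTRUE(record$valid)) stop("cannot profile an invalid record")
  mol <- record$mol
  if (is.null(ob)) ob <- ob_properties(record$smiles_canonical)
  ncarb <- sum(mol$atoms$element == "C")
  qcf <- if (ncarb == 0L) 0 else sum(chiral_carbon_flags(mol)) / ncarb
  wi <- tryCatch(wiener_index(mol), error = function(e) NA_real_)
  c(MW = mol_weight(mol),
    NR = ring_count(mol),
    NH = n_heteroatoms(mol),
    QCF = qcf,
    HCF = fraction_csp3(mol),
    BI = bertz_index_degree(mol),
    HI = hann_index(mol),
    WI = wi,
    QED = qed(record, ob = ob),
    PCI = unname(pci(record, ob = ob)))
}

#' Mean absolute parent-mutant complexity differences
#'
#' For aligned parent/mutant pairs, computes the per-field mean of
#' `|value(parent) - value(mutant)|` over pairs whose mutant is valid -
#' the magnitude-only convention used throughout the benchmark. Fields
#' that are `NA` on either side of a pair (e.g. Wiener on a disconnected
#' fragment) are dropped from that field's mean.
#'
#' @param parents list of valid `molecule_record`s.
#' @param mutants list of `molecule_record`s or `mutation_record`s aligned
#'   with `parents` (same length; pairing is positional, with `parent_id`
#'   consistency checked for mutation records).
#' @param fields subset of profile fields (default all ten).
#' @param operator,k optional labels stored in the summary.
#' @return object of class `delta_summary`: named means plus `n_pairs`.
#' @export
delta_summary <- function(parents, mutants, fields = .COMPLEXITY_FIELDS,
                          operator = NA_character_, k = NA_integer_) {
  stopifnot(length(parents) == length(mutants))
  fields <- match.arg(fields, .COMPLEXITY_FIELDS, several.ok = TRUE)
  pairs <- list()
  for (i in seq_along(parents)) {
    p <- parents[[i]]
    m <- mutants[[i]]
    if (inherits(m, "mutation_record")) {
      if (!is.na(m$parent_id) && !identical(m$parent_id, p$id)) {
        stop("parent/mutant pairing mismatch at position ", i)
      }
      m <- m$record
    }
    if (isTRUE(p$valid) && isTRUE(m$valid)) {
      pairs[[length(pairs) + 1L]] <- list(p = p, m = m)
    }
  }
  if (!length(pairs)) stop("empty-aggregate: no valid parent/mutant pairs")
  psm <- vapply(pairs, function(x) x$p$smiles_canonical, "")
  msm <- vapply(pairs, function(x) x$m$smiles_canonical, "")
  ob <- ob_properties(c(psm, msm))
  np <- length(pairs)
  deltas <- matrix(NA_real_, np, length(fields), dimnames = list(NULL, fields))
  for (j in seq_len(np)) {
    cp <- complexity_profile(pairs[[j]]$p, ob = ob[j, , drop = FALSE])
    cm <- complexity_profile(pairs[[j]]$m, ob = ob[np + j, , drop = FALSE])
    deltas[j, ] <- abs(cp[fields] - cm[fields])
  }
  means <- colMeans(deltas, na.rm = TRUE)
  structure(list(operator = operator, k = k, mean_abs_delta = means,
                 n_pairs = np), class = "delta_summary")
}

#' @export
print.delta_summary <- function(x, ...) {
  cat(sprintf("<delta_summary%s%s> %d valid pairs\n",
              if (is.na(x$operator)) "" else paste0(" ", x$operator),
              if (is.na(x$k)) "" else sprintf(" k=%d", x$k), x$n_pairs))
  print(round(x$mean_abs_delta, 4))
  invisible(x)
}
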