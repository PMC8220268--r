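# Biogeographic Connectedness (BC) and its phylogenetically corrected form
# (pBC) on taxon x region incidence structures.
#
# BC = (O - N) / (L*N - N) where O is the number of (weighted) occupancy
# links, N the number of taxa, L the number of regions: 0 = complete
# endemism, 1 = complete cosmopolitanism. pBC fills the binary matrix with
# partial occupancy exp(-d/mu), where d is the patristic distance from a
# taxon to the phylogenetically nearest occupant of the region and mu (Myr)
# is the e-folding decay constant; as mu -> 0 pBC collapses to BC, as
# mu -> Inf it tends to 1.

#' Build a taxon-by-region incidence matrix
#'
#' Collapses occurrence records to binary occupancy within one time bin.
#' Records whose `time_bin` field lists several bins (separated by `;`,
#' e.g. a taxon whose stratigraphic range crosses a bin boundary) count in
#' every listed bin. Declared regions never occupied in the bin are dropped,
#' since connectedness is defined on occupied regions.
#'
#' @param occurrences A data frame of occurrence records with at least
#'   columns `taxon` and `region`, and `time_bin` if `time_bin` is given.
#' @param time_bin Optional name of the time bin to restrict to.
#' @param regions Optional character vector declaring the region set (column
#'   order of the result); defaults to the regions observed.
#' @return An integer matrix with taxa as row names and regions as column
#'   names.
#' @examples
#' occ <- tibble::tibble(
#'   taxon = c("A", "B", "C", "C"),
#'   region = c("north", "south", "north", "south"),
#'   time_bin = "Campanian"
#' )
#' build_incidence(occ, "Campanian")
#' @export
build_incidence <- function(occurrences, time_bin = NULL, regions = NULL) {
  stopifnot(is.data.frame(occurrences))
  need <- c("taxon", "region", if (!is.null(time_bin)) "time_bin")
  miss <- setdiff(need, names(occurrences))
  if (length(miss) > 0) {
    abort(paste0("`occurrences` lacks columns: ", paste(miss, collapse = ", ")))
  }
  df <- occurrences
  if (!is.null(time_bin)) {
    df <- tidyr::separate_rows(df, "time_bin", sep = ";")
    df <- df[trimws(df$time_bin) == time_bin, , drop = FALSE]
  }
  df <- dplyr::distinct(df, .data$taxon, .data$region)
  taxa <- sort(unique(df$taxon))
  regs <- regions %||% sort(unique(df$region))
  unknown <- setdiff(df$region, regs)
  if (length(unknown) > 0) {
    abort(paste0("Regions outside the declared set: ", paste(unique(unknown), collapse = ", ")))
  }
  M <- matrix(0L, nrow = length(taxa), ncol = length(regs),
              dimnames = list(taxa, regs))
  M[cbind(match(df$taxon, taxa), match(df$region, regs))] <- 1L
  M <- M[, colSums(M) > 0, drop = FALSE]
  if (nrow(M) < 2 || ncol(M) < 2) {
    abort("insufficient data for connectedness: need >= 2 taxa occupying >= 2 regions")
  }
  M
}

check_incidence <- function(inc) {
  if (!is.matrix(inc) || is.null(rownames(inc)) || is.null(colnames(inc))) {
    abort("`inc` must be a labelled taxon x region matrix (see build_incidence()).")
  }
  if (ncol(inc) < 2) abort("Connectedness is undefined for a single region.")
  if (nrow(inc) < 2) abort("Connectedness needs at least two taxa.")
  if (any(rowSums(inc > 0) == 0)) abort("Every taxon must occupy at least one region.")
  invisible(TRUE)
}

pbc_tibble <- function(statistic, O, N, L, mu) {
  tibble(
    statistic = statistic,
    value = (O - N) / (L * N - N),
    O = O, N = N, L = L, mu = mu
  )
}

#' Classic (binary) Biogeographic Connectedness
#'
#' @param inc A taxon-by-region incidence matrix from [build_incidence()].
#' @return A one-row tibble with columns `statistic`, `value`, `O`, `N`, `L`,
#'   `mu` (`NA` for the unweighted statistic).
#' @export
compute_bc <- function(inc) {
  check_incidence(inc)
  pbc_tibble("BC", O = sum(inc > 0), N = nrow(inc), L = ncol(inc), mu = NA_real_)
}

# Weighted occupancy matrix: for each region, each taxon's link weight is
# exp(-d/mu) to the nearest occupant of that region (1 for occupants).
pbc_weights <- function(inc, dist, mu) {
  W <- matrix(NA_real_, nrow(inc), ncol(inc), dimnames = dimnames(inc))
  for (k in seq_len(ncol(inc))) {
    occ <- which(inc[, k] > 0)
    dmin <- do.call(pmin, lapply(occ, function(j) dist[, j]))
    W[, k] <- pmax(inc[, k], exp(-dmin / mu))
  }
  W
}

#' Phylogenetically corrected Biogeographic Connectedness (pBC)
#'
#' Weighted form of [compute_bc()]: a taxon absent from a region contributes
#' a partial occupancy link `exp(-d/mu)` where `d` is its patristic distance
#' to the nearest taxon occupying that region.
#'
#' @inheritParams compute_bc
#' @param dist A patristic distance matrix covering all taxa in `inc`
#'   (see [patristic_matrix()]), in Myr.
#' @param mu Decay constant in Myr (> 0). Default 10.
#' @return A one-row tibble (see [compute_bc()]).
#' @examples
#' inc <- matrix(c(1L, 0L, 1L, 0L, 1L, 0L), 3,
#'   dimnames = list(c("A", "B", "C"), c("north", "south"))
#' )
#' d <- matrix(c(0, 20, 10, 20, 0, 20, 10, 20, 0), 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
#' )
#' compute_pbc(inc, d, mu = 10) # value = exp(-2) = 0.13534
#' @export
compute_pbc <- function(inc, dist, mu = 10) {
  check_incidence(inc)
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu <= 0) {
    abort("`mu` must be a single positive number (Myr).")
  }
  missing_taxa <- setdiff(rownames(inc), rownames(dist))
  if (length(missing_taxa) > 0) {
    abort(paste0(
      "Taxa missing from the distance matrix: ",
      paste(missing_taxa, collapse = ", ")
    ))
  }
  D <- dist[rownames(inc), rownames(inc), drop = FALSE]
  W <- pbc_weights(inc, D, mu)
  pbc_tibble("pBC", O = sum(W), N = nrow(inc), L = ncol(inc), mu = mu)
}

#' Sensitivity of pBC to the decay constant
#'
#' Recomputes pBC across a sweep of `mu` values (the statistic is monotone
#' non-decreasing in `mu`).
#'
#' @inheritParams compute_pbc
#' @param mus Numeric vector of decay constants (Myr), all > 0. Default 1:15.
#' @return A tibble with one row per `mu`, sorted by `mu`.
#' @export
mu_sweep <- function(inc, dist, mus = 1:15) {
  if (length(mus) == 0 || any(!is.finite(mus)) || any(mus <= 0)) {
    abort("`mus` must be a non-empty vector of positive values.")
  }
  purrr::map_dfr(sort(mus), function(m) compute_pbc(inc, dist, mu = m))
}
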