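#' Ft-Ds kinetic parameters
#'
#' Rates are per minute and converted to per-step probabilities as
#' `1 - exp(-k * dt)`, so halving or doubling the step length needs no
#' re-tuning. Binding weights give the probability that a drawn Ft-Ds pair
#' actually forms a heterodimer, by phosphorylation state: phosphorylation by
#' Fj makes Ft more likely (0.05 -> 0.7) and Ds less likely (0.05, 0.2 for
#' phosphorylated Ds) to bind.
#'
#' @param k_dissoc Bond dissociation rate (default 0.08/min).
#' @param k_deg_ft,k_deg_ds Degradation rates of *free* Ft and Ds (default
#'   0.08/min each); bound protein is protected.
#' @param k_dephos Dephosphorylation rate of free phosphorylated Ft/Ds
#'   (default 0.02/min, slow enough that phosphorylation state is a memory).
#' @param ft_rate Constant Ft expression rate, proteins/min (uniform across
#'   the disc).
#' @param w Named binding weights `uu`, `up`, `pu`, `pp` (Ft state first:
#'   `pu` is phosphorylated Ft with unphosphorylated Ds). Defaults 0.05,
#'   0.05, 0.7, 0.2.
#' @param phos_K Fj level at which half of newly made protein is
#'   phosphorylated (a.u.).
#' @return A list of class `fatds_kinetics`.
#' @export
kinetic_params <- function(k_dissoc = 0.08, k_deg_ft = 0.08, k_deg_ds = 0.08,
                           k_dephos = 0.02, ft_rate = 20,
                           w = c(uu = 0.05, up = 0.05, pu = 0.7, pp = 0.2),
                           phos_K = 0.5) {
  stopifnot(all(c("uu", "up", "pu", "pp") %in% names(w)),
            all(w >= 0 & w <= 1),
            k_dissoc >= 0, k_deg_ft >= 0, k_deg_ds >= 0, k_dephos >= 0,
            ft_rate >= 0, phos_K > 0)
  if (w[["pu"]] <= w[["uu"]] || w[["up"]] > w[["uu"]]) {
    abort("Binding weights must satisfy pu > uu and up <= uu (Fj raises Ft's and lowers Ds's affinity).")
  }
  structure(list(k_dissoc = k_dissoc, k_deg_ft = k_deg_ft,
                 k_deg_ds = k_deg_ds, k_dephos = k_dephos, ft_rate = ft_rate,
                 w = w[c("uu", "up", "pu", "pp")], phos_K = phos_K),
            class = "fatds_kinetics")
}

.check_pools <- function(pools) {
  need <- c("ft_u", "ft_p", "ds_u", "ds_p")
  if (!all(need %in% names(pools))) {
    abort("`pools` needs columns ft_u, ft_p, ds_u, ds_p.")
  }
  pools
}

#' Express new Ft and Ds protein
#'
#' Adds `Poisson(ft_rate * dt)` Ft and `Poisson(ds_rate * dt)` Ds to each
#' cell's free pools. Each *newly produced* protein is phosphorylated
#' independently with probability `fj / (fj + phos_K)`; protein already at the
#' membrane is never phosphorylated after the fact (Fj acts in the Golgi).
#'
#' @param pools A data frame with columns `ft_u`, `ft_p`, `ds_u`, `ds_p`
#'   (one row per cell).
#' @param fj_level Fj level per cell (a.u.).
#' @param ds_rate Ds expression rate per cell (proteins/min).
#' @param params [kinetic_params()].
#' @param dt Minutes per step.
#' @return `pools` updated; attributes `produced_ft` and `produced_ds` hold
#'   the per-cell production counts.
#' @export
express_proteins <- function(pools, fj_level, ds_rate,
                             params = kinetic_params(), dt = 1) {
  pools <- .check_pools(pools)
  n <- length(pools$ft_u)
  if (any(ds_rate < 0) || params$ft_rate < 0) abort("Expression rates must be >= 0.")
  new_ft <- rpois(n, params$ft_rate * dt)
  new_ds <- rpois(n, ds_rate * dt)
  p_phos <- fj_level / (fj_level + params$phos_K)
  ft_p_new <- rbinom(n, new_ft, p_phos)
  ds_p_new <- rbinom(n, new_ds, p_phos)
  pools$ft_u <- pools$ft_u + new_ft - ft_p_new
  pools$ft_p <- pools$ft_p + ft_p_new
  pools$ds_u <- pools$ds_u + new_ds - ds_p_new
  pools$ds_p <- pools$ds_p + ds_p_new
  attr(pools, "produced_ft") <- new_ft
  attr(pools, "produced_ds") <- new_ds
  pools
}

.split_even <- function(count, k) {
  count <- as.integer(round(count))
  alloc <- rep(count %/% k, k)
  rem <- count %% k
  if (rem > 0L) {
    idx <- sample.int(k, rem)
    alloc[idx] <- alloc[idx] + 1L
  }
  alloc
}

#' Partition a cell's free protein evenly among its interfaces
#'
#' Each of the four free pools is split into `n_neighbors` integer shares
#' differing by at most one; the remainder is handed to uniformly random
#' interfaces. With zero neighbors nothing is allocated.
#'
#' @param pools A single cell's pools: named numeric (or one-row data frame)
#'   with `ft_u`, `ft_p`, `ds_u`, `ds_p`.
#' @param n_neighbors Number of interfaces.
#' @return A matrix with `n_neighbors` rows and columns `ft_u`, `ft_p`,
#'   `ds_u`, `ds_p`; columns sum to the pool sizes.
#' @export
partition_free <- function(pools, n_neighbors) {
  pools <- as.list(pools)
  .check_pools(pools)
  if (n_neighbors < 0) abort("`n_neighbors` must be >= 0.")
  n_neighbors <- as.integer(n_neighbors)
  if (n_neighbors == 0L) {
    return(matrix(0, 0, 4, dimnames = list(NULL, c("ft_u", "ft_p", "ds_u", "ds_p"))))
  }
  out <- vapply(c("ft_u", "ft_p", "ds_u", "ds_p"),
                function(p) .split_even(pools[[p]], n_neighbors),
                integer(n_neighbors))
  if (n_neighbors == 1L) out <- matrix(out, 1, 4,
    dimnames = list(NULL, c("ft_u", "ft_p", "ds_u", "ds_p")))
  out
}

#' Form Ft-Ds bonds at one interface
#'
#' Pairs the Ft allocated by one cell with the Ds allocated by its neighbor:
#' `K = min(total Ft, total Ds)` independent attempts, each drawing an Ft and
#' a Ds uniformly without replacement from the allocations, succeeding with
#' the state-dependent weight `w`. Proteins drawn into failed attempts (and
#' unpaired surplus) return to the free pool. The random pairing is realized
#' by hypergeometric draws of how many phosphorylated molecules enter the
#' attempts and how they cross-match.
#'
#' @param alloc_ft Named counts `u`, `p`: Ft allocated by the Ft-side cell.
#' @param alloc_ds Named counts `u`, `p`: Ds allocated by the Ds-side cell.
#' @param w Binding weights as in [kinetic_params()].
#' @param stochastic When `FALSE`, expected attempt counts are used and
#'   successes are rounded expectations (deterministic mode for tests).
#' @return List with `bonds` (named counts `uu`, `up`, `pu`, `pp`),
#'   `leftover_ft`, `leftover_ds` (named `u`/`p` counts returning free).
#' @export
form_bonds <- function(alloc_ft, alloc_ds, w = kinetic_params()$w,
                       stochastic = TRUE) {
  fu <- alloc_ft[["u"]]; fp <- alloc_ft[["p"]]
  du <- alloc_ds[["u"]]; dp <- alloc_ds[["p"]]
  if (any(c(fu, fp, du, dp) < 0)) abort("Allocations must be >= 0.")
  FT <- fu + fp; DS <- du + dp
  K <- min(FT, DS)
  if (K == 0) {
    zero <- c(uu = 0, up = 0, pu = 0, pp = 0)
    return(list(bonds = zero, leftover_ft = c(u = fu, p = fp),
                leftover_ds = c(u = du, p = dp)))
  }
  if (stochastic) {
    fp_in <- rhyper(1, fp, fu, K)   # phosphorylated Ft entering attempts
    dp_in <- rhyper(1, dp, du, K)
    pp_att <- rhyper(1, dp_in, K - dp_in, fp_in)  # FtP randomly matched to DsP
    pu_att <- fp_in - pp_att
    up_att <- dp_in - pp_att
    uu_att <- K - fp_in - up_att
    att <- c(uu = uu_att, up = up_att, pu = pu_att, pp = pp_att)
    bonds <- rbinom(4, att, w[c("uu", "up", "pu", "pp")])
    names(bonds) <- names(att)
  } else {
    fp_in <- K * fp / FT; dp_in <- K * dp / DS
    att <- c(uu = (K - fp_in) * (K - dp_in) / K,
             up = (K - fp_in) * dp_in / K,
             pu = fp_in * (K - dp_in) / K,
             pp = fp_in * dp_in / K)
    bonds <- round(att * w[c("uu", "up", "pu", "pp")])
  }
  ft_used <- c(u = unname(bonds[["uu"]] + bonds[["up"]]),
               p = unname(bonds[["pu"]] + bonds[["pp"]]))
  ds_used <- c(u = unname(bonds[["uu"]] + bonds[["pu"]]),
               p = unname(bonds[["up"]] + bonds[["pp"]]))
  list(bonds = bonds,
       leftover_ft = c(u = fu, p = fp) - ft_used,
       leftover_ds = c(u = du, p = dp) - ds_used)
}

#' Dissolve Ft-Ds bonds
#'
#' Each bond dissolves independently with probability `1 - exp(-k_dissoc *
#' dt)` (binomial thinning per phosphorylation type). Released proteins
#' return to their owners' free pools with their state preserved.
#'
#' @param bonds A matrix or data frame of bond counts with columns `uu`,
#'   `up`, `pu`, `pp` (rows are interfaces).
#' @param k_dissoc Dissociation rate per minute.
#' @param dt Minutes per step.
#' @return List with `bonds` (surviving counts) and `released` (dissolved
#'   counts, same shape).
#' @export
dissolve_bonds <- function(bonds, k_dissoc, dt = 1) {
  b <- as.matrix(bonds)
  p <- .rate_to_prob(k_dissoc, dt)
  if (p > 1) abort("k_dissoc * dt gives a probability above 1.")
  rel <- matrix(rbinom(length(b), as.integer(b), p), nrow(b), ncol(b),
                dimnames = dimnames(b))
  list(bonds = b - rel, released = rel)
}

#' Degrade free Ft and Ds
#'
#' Binomial thinning of the free pools only; bound protein is protected from
#' degradation (endocytosis of receptors requires them to be unbound).
#'
#' @inheritParams express_proteins
#' @param k_deg_ft,k_deg_ds Degradation rates per minute.
#' @return `pools` thinned; attributes `degraded_ft`, `degraded_ds` hold
#'   per-cell totals.
#' @export
degrade_free <- function(pools, k_deg_ft, k_deg_ds, dt = 1) {
  pools <- .check_pools(pools)
  p_ft <- .rate_to_prob(k_deg_ft, dt)
  p_ds <- .rate_to_prob(k_deg_ds, dt)
  n <- length(pools$ft_u)
  d_fu <- rbinom(n, as.integer(pools$ft_u), p_ft)
  d_fp <- rbinom(n, as.integer(pools$ft_p), p_ft)
  d_du <- rbinom(n, as.integer(pools$ds_u), p_ds)
  d_dp <- rbinom(n, as.integer(pools$ds_p), p_ds)
  pools$ft_u <- pools$ft_u - d_fu
  pools$ft_p <- pools$ft_p - d_fp
  pools$ds_u <- pools$ds_u - d_du
  pools$ds_p <- pools$ds_p - d_dp
  attr(pools, "degraded_ft") <- d_fu + d_fp
  attr(pools, "degraded_ds") <- d_du + d_dp
  pools
}

#' Dephosphorylate free protein
#'
#' Free phosphorylated Ft and Ds revert to the unphosphorylated state by
#' binomial thinning; bound protein keeps its state. Totals are conserved.
#'
#' @inheritParams express_proteins
#' @param k_dephos Dephosphorylation rate per minute.
#' @return `pools` with mass moved from `ft_p` to `ft_u` and `ds_p` to `ds_u`.
#' @export
dephosphorylate <- function(pools, k_dephos, dt = 1) {
  pools <- .check_pools(pools)
  p <- .rate_to_prob(k_dephos, dt)
  n <- length(pools$ft_u)
  m_ft <- rbinom(n, as.integer(pools$ft_p), p)
  m_ds <- rbinom(n, as.integer(pools$ds_p), p)
  pools$ft_p <- pools$ft_p - m_ft
  pools$ft_u <- pools$ft_u + m_ft
  pools$ds_p <- pools$ds_p - m_ds
  pools$ds_u <- pools$ds_u + m_ds
  pools
}
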