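#' Approximate pedigree-based reliabilities
#'
#' Iterative approximation of animal-model reliabilities from the pedigree and
#' per-animal record information, without inverting the mixed-model equations.
#' Each animal's information is tracked in record equivalents (ERC) from three
#' sources: own records (`q_own`, fixed), parents (`q_par`) and progeny
#' (`q_prog`), with per-edge bookkeeping so that information an animal sent to
#' a relative in the previous round is excluded when that relative's
#' reliability is used as a source (limits double counting).
#'
#' Each round performs
#' \enumerate{
#'   \item parents-to-progeny, in pedigree order: the parent-average
#'     reliability `rel_PA = (rel*_s + rel*_d) / 4` where `rel*` is each
#'     parent's reliability excluding the contribution previously received
#'     from this animal (a missing parent contributes 0);
#'     `q_par = alpha * rel_PA / (1 - rel_PA)`.
#'   \item progeny-to-parents, in reverse order: a progeny p of parent s with
#'     mate m contributes the source reliability
#'     `r_src = 0.25 / (0.75 + 0.25 * (1 - rel_m) + alpha / q_p)`, where
#'     `q_p` is p's own-plus-progeny information in record equivalents
#'     (parent contribution excluded) and `rel_m` is the mate's reliability
#'     excluding what p sent to the mate before; the contribution is
#'     `erc_from_rel(r_src, alpha)` and is summed over progeny.  Each
#'     coefficient follows from exact absorption of a two-generation
#'     mixed-model system (a progeny with unlimited records and a perfectly
#'     known mate gives the exact source reliability 1/3; a single-record
#'     progeny with unknown mate gives the exact
#'     `0.25 alpha / (0.75 + alpha)`).
#'   \item `rel = rel_from_erc(q_own + q_par + q_prog, alpha)`.
#' }
#' Rounds repeat until the largest reliability change is below `tol` or
#' `max_rounds` is reached.  Own records contribute for all sexes.
#'
#' @param ped a sorted `pedigree`.
#' @param q_own numeric vector of length `ped$n`: per-animal own-record
#'   information in record equivalents (e.g. the `d_own` column of
#'   [approx_record_information()], or back-solved ERCs).
#' @param alpha variance ratio `sigma_e2 / sigma_u2`.
#' @param max_rounds maximum number of rounds (default 20).
#' @param tol convergence tolerance on reliabilities (default 1e-5).
#' @return list with `rel` (per animal, pedigree order), `q_own`, `q_par`,
#'   `q_prog`, `converged`, `rounds`.  `q_par + q_prog` is the information an
#'   animal receives from relatives; it is what the Steffensen back-solve
#'   holds fixed.
#' @seealso [backsolve_erc_steffensen()], [rel_from_erc()]
#' @export
approx_pedigree_reliability <- function(ped, q_own, alpha,
                                        max_rounds = 20L, tol = 1e-5) {
  check_sorted(ped)
  n <- ped$n
  q_own <- rep_len(as.numeric(q_own), n)
  if (any(q_own < 0)) stop("q_own must be non-negative")
  stopifnot(alpha > 0)
  s <- ped$sire
  d <- ped$dam

  q_par <- numeric(n)
  q_prog <- numeric(n)
  c_sire <- numeric(n)   # contribution animal i sent to its sire last round
  c_dam <- numeric(n)    # contribution animal i sent to its dam last round
  rel <- q_own / (q_own + alpha)
  q_tot <- q_own
  converged <- FALSE
  rounds <- 0L

  rel_minus <- function(qt, c_excl) {
    q <- max(0, qt - c_excl)
    q / (q + alpha)
  }

  for (round in seq_len(max_rounds)) {
    rounds <- round
    rel_old <- rel

    # (a) parents -> progeny, pedigree order (parents already updated)
    for (i in seq_len(n)) {
      rs <- if (is.na(s[i])) 0 else rel_minus(q_own[s[i]] + q_par[s[i]] + q_prog[s[i]], c_sire[i])
      rd <- if (is.na(d[i])) 0 else rel_minus(q_own[d[i]] + q_par[d[i]] + q_prog[d[i]], c_dam[i])
      rel_pa <- (rs + rd) / 4
      q_par[i] <- alpha * rel_pa / (1 - rel_pa)
    }

    # (b) progeny -> parents, reverse order (younger families absorbed first)
    q_prog_new <- numeric(n)
    c_sire_new <- numeric(n)
    c_dam_new <- numeric(n)
    for (p in n:1) {
      if (is.na(s[p]) && is.na(d[p])) next
      q_p <- q_own[p] + q_prog_new[p]
      if (q_p <= 0) next
      if (!is.na(s[p])) {
        rm <- if (is.na(d[p])) 0 else rel_minus(q_tot[d[p]], c_dam[p])
        r_src <- 0.25 / (0.75 + 0.25 * (1 - rm) + alpha / q_p)
        c_sire_new[p] <- alpha * r_src / (1 - r_src)
        q_prog_new[s[p]] <- q_prog_new[s[p]] + c_sire_new[p]
      }
      if (!is.na(d[p])) {
        rm <- if (is.na(s[p])) 0 else rel_minus(q_tot[s[p]], c_sire[p])
        r_src <- 0.25 / (0.75 + 0.25 * (1 - rm) + alpha / q_p)
        c_dam_new[p] <- alpha * r_src / (1 - r_src)
        q_prog_new[d[p]] <- q_prog_new[d[p]] + c_dam_new[p]
      }
    }
    q_prog <- q_prog_new
    c_sire <- c_sire_new
    c_dam <- c_dam_new

    # (c) combine the three sources
    q_tot <- q_own + q_par + q_prog
    rel <- q_tot / (q_tot + alpha)

    if (max(abs(rel - rel_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("pedigree reliability approximation did not converge in ",
            max_rounds, " rounds")
  list(rel = rel, q_own = q_own, q_par = q_par, q_prog = q_prog,
       converged = converged, rounds = rounds)
}

#' Back-solve an effective record contribution by Steffensen's method
#'
#' Finds the own-information `q >= 0` such that `forward_map(q)` equals a
#' target reliability, using Steffensen iteration
#' `x' = x - f(x)^2 / (f(x + f(x)) - f(x))` with
#' `f(x) = forward_map(x) - target_rel`.  Derivative-free, quadratically
#' convergent near the root; falls back to bisection with a doubling upper
#' bound if the Steffensen denominator underflows or an iterate leaves
#' `[0, Inf)` without converging.
#'
#' If the target is at or below `forward_map(0)` (the reliability an animal
#' has with no own information), `q = 0` is returned.
#'
#' @param target_rel target reliability in `[0, 1)`.
#' @param forward_map monotone increasing function mapping own-information q
#'   to a reliability, all other animals' states held fixed.
#' @param q0 initial guess; defaults to `erc_from_rel(target_rel, alpha)` when
#'   `alpha` is given, else `target_rel / (1 - target_rel)`.
#' @param tol tolerance on `|forward_map(q) - target_rel|` (default 1e-8).
#' @param max_iter maximum iterations (default 50).
#' @param alpha optional variance ratio used only for the default `q0`.
#' @return list with `q`, `rel` (achieved), `iterations`, `converged`,
#'   `method` (`"steffensen"` or `"bisection"`).
#' @export
backsolve_erc_steffensen <- function(target_rel, forward_map, q0 = NULL,
                                     tol = 1e-8, max_iter = 50L,
                                     alpha = NULL) {
  if (target_rel < 0 || target_rel >= 1)
    stop("target reliability must lie in [0, 1)")
  if (forward_map(0) >= target_rel - tol)
    return(list(q = 0, rel = forward_map(0), iterations = 0L,
                converged = TRUE, method = "clamp"))
  if (is.null(q0))
    q0 <- if (!is.null(alpha)) erc_from_rel(target_rel, alpha)
          else target_rel / (1 - target_rel)

  f <- function(x) forward_map(x) - target_rel
  x <- max(q0, 0)
  for (it in seq_len(max_iter)) {
    fx <- f(x)
    if (abs(fx) < tol)
      return(list(q = x, rel = fx + target_rel, iterations = it - 1L,
                  converged = TRUE, method = "steffensen"))
    gx <- f(x + fx)
    den <- gx - fx
    if (!is.finite(den) || abs(den) < .Machine$double.eps * (1 + abs(fx)))
      break
    x_new <- x - fx^2 / den
    if (!is.finite(x_new) || x_new < 0) break
    x <- x_new
  }
  # bisection fallback with doubling upper bound
  lo <- 0
  hi <- max(q0, 1)
  grow <- 0L
  while (f(hi) < 0 && grow < 60L) {
    hi <- hi * 2
    grow <- grow + 1L
  }
  if (f(hi) < 0)
    return(list(q = hi, rel = forward_map(hi), iterations = max_iter,
                converged = FALSE, method = "bisection"))
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol)
      return(list(q = mid, rel = fm + target_rel, iterations = it,
                  converged = TRUE, method = "bisection"))
    if (fm < 0) lo <- mid else hi <- mid
  }
  list(q = (lo + hi) / 2, rel = forward_map((lo + hi) / 2),
       iterations = 200L, converged = FALSE, method = "bisection")
}
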