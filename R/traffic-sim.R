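#' CargoSystem: cargo mix competing for bulk flow and a shared receptor
#'
#' Deterministic mass-action description of soluble cargo in the ER lumen.
#' Each cargo i is synthesized at rate \eqn{s_i}, leaves by receptor-
#' independent bulk flow at rate \eqn{k_{bulk} C_i}, and by saturable,
#' competitively shared receptor export
#' \deqn{v_i = V_r \frac{C_i/K_{d,i}}{1 + \sum_j C_j/K_{d,j}}}
#' (single pooled receptor under quasi-steady-state binding; a cargo with
#' \eqn{K_d = \infty} never binds). \eqn{C_{agg,i}} is the concentration
#' above which the cargo forms intralumenal aggregates
#' (\eqn{\infty} = non-aggregator). Units are abstract
#' (nondimensionalized concentration and time).
#'
#' @slot cargo data.frame with columns `name`, `synthesis` (> 0), `kd`
#'   (> 0 or Inf) and `c_agg` (> 0 or Inf).
#' @slot kBulk bulk-flow rate constant (> 0, time^-1).
#' @slot vr receptor export capacity (>= 0, amount/time; proportional to
#'   total receptor).
#' @seealso [cargoSystem()], [solveSteadyState()]
#' @export
setClass("CargoSystem",
  representation(cargo = "data.frame", kBulk = "numeric", vr = "numeric"))

setValidity("CargoSystem", function(object) {
  msg <- character()
  d <- object@cargo
  if (!all(c("name", "synthesis", "kd", "c_agg") %in% names(d)))
    return("cargo must have columns name, synthesis, kd, c_agg")
  if (!nrow(d)) msg <- c(msg, "at least one cargo required")
  if (anyDuplicated(d$name)) msg <- c(msg, "cargo names must be unique")
  if (any(d$synthesis <= 0)) msg <- c(msg, "synthesis rates must be > 0")
  if (any(d$kd <= 0)) msg <- c(msg, "kd must be > 0 (Inf = nonbinder)")
  if (any(d$c_agg <= 0)) msg <- c(msg, "c_agg must be > 0 (Inf = non-aggregator)")
  if (length(object@kBulk) != 1L || object@kBulk <= 0)
    msg <- c(msg, "kBulk must be a single value > 0")
  if (length(object@vr) != 1L || object@vr < 0)
    msg <- c(msg, "vr must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CargoSystem
#'
#' @param cargo data.frame with columns `name`, `synthesis`, `kd`,
#'   `c_agg` (the latter two may be `Inf` for nonbinders /
#'   non-aggregators; `c_agg` defaults to `Inf` if absent).
#' @param kBulk bulk-flow rate constant (time^-1).
#' @param vr receptor export capacity (amount/time).
#' @return A [CargoSystem-class].
#' @examples
#' sys <- cargoSystem(data.frame(name = c("APV", "EET"),
#'                               synthesis = c(1, 1),
#'                               kd = c(0.2, Inf)),
#'                    kBulk = 0.1, vr = 2)
#' solveSteadyState(sys)
#' @export
cargoSystem <- function(cargo, kBulk, vr) {
  cargo <- as.data.frame(cargo)
  if (!"c_agg" %in% names(cargo)) cargo$c_agg <- Inf
  new("CargoSystem", cargo = cargo, kBulk = kBulk, vr = vr)
}

setMethod("show", "CargoSystem", function(object) {
  cat("CargoSystem:", nrow(object@cargo), "cargo, kBulk =", object@kBulk,
      ", Vr =", object@vr, "\n")
  print(object@cargo)
  invisible(object)
})

## balance function F(C) = s - kBulk*C - Vr*(C/Kd)/(1+sum(C/Kd)); roots are
## the steady state. Returns list(f, jacobian).
.balance <- function(C, s, kb, vr, kd) {
  x <- C / kd                      # Inf kd -> 0 occupancy pressure
  S <- sum(x)
  denom <- 1 + S
  f <- s - kb * C - vr * x / denom
  n <- length(C)
  J <- diag(-kb, n)
  if (vr > 0) {
    invkd <- 1 / kd
    ## d/dCj [ (Ci/Kdi) / (1+S) ] = dij/Kdi/(1+S) - (Ci/Kdi)/Kdj/(1+S)^2
    J <- J - vr * (diag(invkd / denom, n) -
                   outer(x, invkd) / denom^2)
  }
  list(f = f, J = J)
}

#' Solve the cargo steady state
#'
#' Finds the non-negative root of the coupled balance equations
#' \eqn{s_i = k_{bulk} C_i^* + V_r (C_i^*/K_{d,i})/(1+\sum_j C_j^*/K_{d,j})}
#' by damped Newton iteration with a positivity projection, run from two
#' independent starting points (the bulk-only solution and near zero) with
#' a built-in agreement check; a conservative fixed-point fallback handles
#' the rare Newton failure. With \eqn{V_r = 0} the solution reduces
#' exactly to the bulk-only closed form \eqn{C_i^* = s_i/k_{bulk}}.
#'
#' @param system a [CargoSystem-class].
#' @param tol residual tolerance for convergence (default 1e-10 relative
#'   to synthesis rates).
#' @param maxit maximum Newton iterations per start.
#' @return A [S4Vectors::DataFrame] with per-cargo `name`, `conc`
#'   (steady-state ER concentration), `flux_bulk`, `flux_receptor`,
#'   `aggregated` (conc >= c_agg, inclusive) and `margin`
#'   (c_agg - conc); solver diagnostics in `metadata()`:
#'   `converged`, `residual`, `iterations`, `start_agreement`.
#' @export
solveSteadyState <- function(system, tol = 1e-10, maxit = 200L) {
  stopifnot(is(system, "CargoSystem"))
  d <- system@cargo
  s <- d$synthesis; kb <- system@kBulk; vr <- system@vr; kdv <- d$kd
  scale <- max(abs(s))
  solveFrom <- function(C0) {
    C <- C0
    for (it in seq_len(maxit)) {
      bal <- .balance(C, s, kb, vr, kdv)
      res <- max(abs(bal$f)) / scale
      if (res < tol) return(list(C = C, res = res, it = it, ok = TRUE))
      step <- tryCatch(solve(bal$J, -bal$f), error = function(e) NULL)
      if (is.null(step)) return(list(C = C, res = res, it = it, ok = FALSE))
      lam <- 1
      f0 <- sum(bal$f^2)
      repeat {
        Cn <- pmax(C + lam * step, 0)
        fn <- sum(.balance(Cn, s, kb, vr, kdv)$f^2)
        if (fn < f0 || lam < 1e-8) break
        lam <- lam / 2
      }
      C <- Cn
    }
    bal <- .balance(C, s, kb, vr, kdv)
    list(C = C, res = max(abs(bal$f)) / scale, it = maxit,
         ok = max(abs(bal$f)) / scale < tol)
  }
  ## fixed-point fallback: damped pseudo-time relaxation
  relaxFrom <- function(C0) {
    C <- C0
    h <- 0.5 / kb
    for (it in seq_len(50000L)) {
      f <- .balance(C, s, kb, vr, kdv)$f
      res <- max(abs(f)) / scale
      if (res < tol) return(list(C = C, res = res, it = it, ok = TRUE))
      C <- pmax(C + h * f, 0)
    }
    list(C = C, res = res, it = 50000L, ok = FALSE)
  }
  bulkOnly <- s / kb
  r1 <- solveFrom(bulkOnly)
  r2 <- solveFrom(rep(1e-6 * scale / kb, length(s)))
  if (!r1$ok) r1 <- relaxFrom(bulkOnly)
  if (!r2$ok) r2 <- relaxFrom(rep(0, length(s)))
  if (!r1$ok || !r2$ok)
    stop("steady-state solver failed to converge; max residual ",
         format(max(r1$res, r2$res)))
  agree <- max(abs(r1$C - r2$C)) / max(max(abs(r1$C)), 1e-300)
  if (agree > 1e-6)
    warning("steady states from independent starts differ by relative ",
            format(agree, digits = 3))
  C <- r1$C
  x <- C / kdv
  recFlux <- if (vr > 0) vr * x / (1 + sum(x)) else rep(0, length(C))
  out <- DataFrame(name = d$name, conc = C,
                   flux_bulk = kb * C, flux_receptor = recFlux,
                   aggregated = C >= d$c_agg, margin = d$c_agg - C)
  S4Vectors::metadata(out) <- list(converged = TRUE, residual = r1$res,
                                   iterations = r1$it,
                                   start_agreement = agree)
  out
}

#' Aggregation flags for a solved steady state
#'
#' Flags every cargo whose steady-state concentration has reached its
#' aggregation threshold (inclusive: a concentration exactly at the
#' threshold is flagged), with the remaining safety margin.
#'
#' @param state output of [solveSteadyState()].
#' @return data.frame with `name`, `conc`, `aggregated`, `margin`.
#' @export
aggregationFlags <- function(state) {
  if (!all(c("name", "conc", "aggregated", "margin") %in% colnames(state)))
    stop("state must be the output of solveSteadyState")
  as.data.frame(state[, c("name", "conc", "aggregated", "margin")])
}

#' Coexpression experiment: does a competitor shift a cargo's steady state?
#'
#' Solves the steady state of a cargo alone and coexpressed with a second
#' cargo under the same bulk-flow and receptor capacity, reporting the
#' relative change in the first cargo's ER concentration. In the
#' receptor-excess regime (receptor capacity large relative to total
#' synthesis demand) coexpression leaves steady states essentially
#' unchanged; when receptor is limiting both concentrations rise.
#'
#' @param strong one-row data.frame (name, synthesis, kd, c_agg) for the
#'   cargo of interest.
#' @param other one-row data.frame for the competitor.
#' @param kBulk bulk-flow rate constant.
#' @param vr receptor export capacity.
#' @return list with `alone` (concentration of `strong` expressed alone),
#'   `coexpressed` (its concentration with the competitor present),
#'   `rel_change`, and the two solved states.
#' @export
coexpressionExperiment <- function(strong, other, kBulk, vr) {
  norm <- function(x) {
    x <- as.data.frame(x)
    if (!"c_agg" %in% names(x)) x$c_agg <- Inf
    x[c("name", "synthesis", "kd", "c_agg")]
  }
  sys1 <- cargoSystem(norm(strong), kBulk, vr)
  sys2 <- cargoSystem(rbind(norm(strong), norm(other)), kBulk, vr)
  st1 <- solveSteadyState(sys1)
  st2 <- solveSteadyState(sys2)
  alone <- st1$conc[1L]
  co <- st2$conc[match(strong$name[1L], st2$name)]
  list(alone = alone, coexpressed = co,
       rel_change = abs(co - alone) / alone,
       state_alone = st1, state_coexpressed = st2)
}

#' Receptor-knockdown experiment: modest:strong concentration ratio
#'
#' Scales the receptor export capacity down by a grid of knockdown factors
#' (1 = no depletion) and reports the steady-state concentration ratio of
#' a modest-affinity cargo to a strong-affinity cargo. Under the
#' competitive receptor-sharing rate law both absolute levels are
#' non-decreasing as capacity falls, and the ratio relaxes monotonically
#' from its receptor-dominated value (bounded above by
#' \eqn{(s_m K_{d,m})/(s_s K_{d,s})}) toward the bulk-only limit
#' \eqn{s_{modest}/s_{strong}} (= 1 for equal synthesis rates): the
#' strong binder, held lowest while receptor is available, loses the most
#' ground when it is depleted. See the package vignette for why this
#' concentration ratio moves opposite to a naive reading of prioritization
#' even though the strong cargo always keeps the larger receptor flux
#' share.
#'
#' @param strong one-row cargo data.frame with the smaller (stronger) kd.
#' @param modest one-row cargo data.frame with larger, finite kd.
#' @param kBulk bulk-flow rate constant.
#' @param vr baseline receptor export capacity.
#' @param factors knockdown grid in (0, 1], default
#'   `c(1, 0.5, 0.2, 0.1, 0.05)`.
#' @return data.frame with one row per factor: `factor`, `vr`,
#'   `conc_strong`, `conc_modest`, `ratio`.
#' @export
knockdownExperiment <- function(strong, modest, kBulk, vr,
                                factors = c(1, 0.5, 0.2, 0.1, 0.05)) {
  if (!(strong$kd[1L] < modest$kd[1L]) || !is.finite(modest$kd[1L]))
    stop("need strong$kd < modest$kd < Inf")
  if (any(factors <= 0) || any(factors > 1))
    stop("knockdown factors must lie in (0, 1]")
  norm <- function(x) {
    x <- as.data.frame(x)
    if (!"c_agg" %in% names(x)) x$c_agg <- Inf
    x[c("name", "synthesis", "kd", "c_agg")]
  }
  cargo <- rbind(norm(strong), norm(modest))
  rows <- lapply(factors, function(f) {
    st <- solveSteadyState(cargoSystem(cargo, kBulk, vr * f))
    cs <- st$conc[match(strong$name[1L], st$name)]
    cm <- st$conc[match(modest$name[1L], st$name)]
    data.frame(factor = f, vr = vr * f, conc_strong = cs,
               conc_modest = cm, ratio = cm / cs)
  })
  do.call(rbind, rows)
}
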