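## Nested-well (sequential two-state) binding model.
##
## Scheme:  unbound  <-- kon1*c / koff1 -->  nonspecific (theta1)
##          nonspecific  <-- kon2 / koff2 -->  specific (theta2)
## Linear rate equations at constant analyte concentration c:
##   dtheta1/dt = kon1*c*(1 - theta1 - theta2) - koff1*theta1
##                - kon2*theta1 + koff2*theta2
##   dtheta2/dt = kon2*theta1 - koff2*theta2

#' Effective dissociation constant of the nested-well system
#'
#' The equilibrium binding of a probe carrying the consensus site involves
#' both the outer (nonspecific) and inner (specific) wells; the measured
#' dissociation constant is \eqn{K_d = K_1 K_2 / (1 + K_2)}, always
#' smaller than the nonspecific \eqn{K_1}.
#'
#' @param object either a \code{\link{RateSet}} or the numeric \code{K1} (nM)
#' @param ... for the numeric method, \code{K2} (dimensionless, > 0)
#' @return effective dissociation constant, nM
#' @examples
#' effectiveKd(200, 0.16)   # 27.59 nM
#' @name effectiveKd
#' @aliases effectiveKd,numeric-method effectiveKd,RateSet-method
NULL

setMethod("effectiveKd", "numeric", function(object, ...) {
  K2 <- list(...)[[1]]
  assertPositiveScalar(object, "K1")
  assertPositiveScalar(K2, "K2")
  object * K2 / (1 + K2)
})

setMethod("effectiveKd", "RateSet", function(object, ...) {
  effectiveKd(K1(object), K2(object))
})

#' Specific-binding coefficient K2 from measured dissociation constants
#'
#' Inverts the nested-well relation \eqn{K_d = K_1 K_2/(1+K_2)}:
#' \eqn{K_2 = K_d/(K_1 - K_d)}.  \code{K2} is the equilibrium ratio of
#' nonspecifically to specifically bound protein, so a small value means
#' most bound protein is docked on the consensus site.
#'
#' @param Kd effective dissociation constant of the specific probe, nM
#' @param K1 dissociation constant of the nonspecific reference, nM
#' @return dimensionless K2
#' @examples
#' k2FromKd(27.59, 200)   # ~0.16
#' @export
k2FromKd <- function(Kd, K1) {
  assertPositiveScalar(Kd, "Kd")
  assertPositiveScalar(K1, "K1")
  if (Kd >= K1)
    nwStop("Kd must be smaller than K1: a probe with a specific site cannot bind more weakly than the nonspecific reference",
           "nwNonphysicalSelectivityError")
  Kd / (K1 - Kd)
}

## A and b of dtheta/dt = A theta + b at concentration c
rateMatrix <- function(c, rates) {
  a <- rates@kon1 * c
  A <- matrix(c(-(a + rates@koff1 + rates@kon2), rates@kon2,
                rates@koff2 - a, -rates@koff2), 2, 2)
  list(A = A, b = c(a, 0))
}

#' Equilibrium occupancy of the nested-well model
#'
#' Steady-state fractions of probe sites in the nonspecific
#' (\code{theta1}) and specific (\code{theta2}) bound states.  The total
#' follows a Langmuir isotherm with the effective dissociation constant,
#' and \code{theta1/theta2 = K2} by detailed balance of the inner step.
#'
#' @param c analyte concentration, nM (vectorised)
#' @param rates a \code{\link{RateSet}}
#' @return data.frame with columns \code{c}, \code{theta1}, \code{theta2}
#' @examples
#' r <- RateSet(1.6e-5, 3.2e-3, 5e-3, 8e-4)
#' equilibriumOccupancy(10, r)
#' @export
equilibriumOccupancy <- function(c, rates) {
  stopifnot(is(rates, "RateSet"))
  if (any(!is.finite(c)) || any(c < 0))
    nwStop("concentrations must be finite and non-negative",
           "nwInvalidParameterError")
  a <- rates@kon1 * c
  if (rates@kon2 <= 0) {
    theta1 <- a / (a + rates@koff1)
    theta2 <- rep(0, length(c))
  } else {
    k2 <- K2(rates)
    den <- a * (1 + k2) + rates@koff1 * k2
    theta1 <- a * k2 / den
    theta2 <- a / den
  }
  data.frame(c = c, theta1 = theta1, theta2 = theta2)
}

#' Relaxation spectrum of the nested-well model after a concentration step
#'
#' After a concentration jump the occupancy relaxes as a double
#' exponential, \eqn{\sigma(c,t) = \Sigma(c)(1 - B e^{-t/\tau_L} -
#' (1-B) e^{-t/\tau_S})}.  The two relaxation times are the negative
#' reciprocal eigenvalues of the 2x2 rate matrix; \code{B} is the
#' amplitude weight of the slow mode for a trace starting empty.  For a
#' single-well probe (\code{kon2 = 0}) the spectrum collapses to one
#' exponential with rate \eqn{\Gamma(c) = k_{on} c + k_{off}}.
#'
#' @param c analyte concentration, nM (scalar)
#' @param rates a \code{\link{RateSet}}
#' @return list with \code{tauS}, \code{tauL} (s, \code{tauS <= tauL}),
#'   \code{B} (slow-mode weight), \code{sigmaEq} (equilibrium bound
#'   fraction), \code{tau1} (single-well reference time
#'   \eqn{1/(k_{on1} c + k_{off1})}) and \code{tauLInf} (fast
#'   inner-exchange limit of \code{tauL})
#' @examples
#' relaxationSpectrum(10, RateSet(1.6e-5, 3.2e-3, 5e-3, 8e-4))
#' @export
relaxationSpectrum <- function(c, rates) {
  stopifnot(is(rates, "RateSet"))
  assertNonNegativeScalar(c, "c")
  a <- rates@kon1 * c
  tau1 <- 1 / (a + rates@koff1)
  if (rates@kon2 <= 0) {
    gam <- a + rates@koff1
    return(list(tauS = 1 / gam, tauL = 1 / gam, B = 1,
                sigmaEq = a / gam, tau1 = tau1, tauLInf = tau1))
  }
  k2 <- K2(rates)
  rm <- rateMatrix(c, rates)
  A <- rm$A
  tr <- A[1, 1] + A[2, 2]
  de <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- tr * tr - 4 * de
  disc <- if (disc < 0) 0 else disc   # guard tiny negative round-off
  rt <- sqrt(disc)
  lamL <- (tr + rt) / 2               # slow eigenvalue (closer to zero)
  lamS <- (tr - rt) / 2
  eq <- equilibriumOccupancy(c, rates)
  sigmaEq <- eq$theta1 + eq$theta2
  tauLInf <- 1 / (a + rates@koff1 * k2 / (1 + k2))
  if (rt <= 1e-10 * abs(tr)) {
    ## critically damped: single decay rate, weight convention B = 1
    return(list(tauS = -1 / lamS, tauL = -1 / lamL, B = 1,
                sigmaEq = sigmaEq, tau1 = tau1, tauLInf = tauLInf))
  }
  ## eigenvectors v(lambda) = (lambda + koff2, kon2)
  vL <- c(lamL + rates@koff2, rates@kon2)
  vS <- c(lamS + rates@koff2, rates@kon2)
  d0 <- -c(eq$theta1, eq$theta2)      # trace starts empty
  detM <- vL[1] * vS[2] - vS[1] * vL[2]
  alphaL <- (d0[1] * vS[2] - vS[1] * d0[2]) / detM
  alphaS <- (vL[1] * d0[2] - d0[1] * vL[2]) / detM
  wL <- alphaL * (vL[1] + vL[2])      # slow-mode contribution to total
  B <- if (sigmaEq > 0) -wL / sigmaEq else 1
  list(tauS = -1 / lamS, tauL = -1 / lamL, B = B,
       sigmaEq = sigmaEq, tau1 = tau1, tauLInf = tauLInf)
}

#' Limiting slow relaxation time under fast inner-well exchange
#'
#' When the inner-well rates grow at fixed ratio \code{K2}, the slow
#' relaxation time approaches
#' \eqn{\tau_{L\infty} = 1/(k_{on1} c + k_{off1} K_2/(1+K_2))}, the escape
#' time of the nonspecifically bound pool held in constant equilibrium
#' with the docked one.  It always exceeds the single-well response time
#' \eqn{\tau_1 = 1/(k_{on1} c + k_{off1})}.
#'
#' @param c analyte concentration, nM
#' @param kon1 association rate, 1/(s nM)
#' @param koff1 nonspecific dissociation rate, 1/s
#' @param K2 specific-binding coefficient, > 0
#' @return limiting slow time, s
#' @examples
#' tauLLimit(10, 1.6e-5, 3.2e-3, 0.16)   # ~1663 s
#' @export
tauLLimit <- function(c, kon1, koff1, K2) {
  assertNonNegativeScalar(c, "c")
  assertPositiveScalar(kon1, "kon1")
  assertPositiveScalar(koff1, "koff1")
  assertPositiveScalar(K2, "K2")
  1 / (kon1 * c + koff1 * K2 / (1 + K2))
}

## ---- piecewise analytic solution ----------------------------------------

## Propagate the state analytically over one constant-concentration step.
## s: state (theta1, theta2) at the step start; tau: times since step
## start (>= 0, vector).  Returns a length(tau) x 2 matrix.
stepSolution <- function(s, c, rates, tau) {
  if (rates@kon2 <= 0) {
    ## single well: theta2 frozen, theta1 relaxes with Gamma = kon1*c + koff1
    a <- rates@kon1 * c
    gam <- a + rates@koff1
    th1eq <- a * (1 - s[2]) / gam
    th1 <- th1eq + (s[1] - th1eq) * exp(-gam * tau)
    return(cbind(th1, rep(s[2], length(tau))))
  }
  rm <- rateMatrix(c, rates)
  A <- rm$A
  tr <- A[1, 1] + A[2, 2]
  de <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- max(tr * tr - 4 * de, 0)
  rt <- sqrt(disc)
  lamL <- (tr + rt) / 2
  lamS <- (tr - rt) / 2
  eq <- equilibriumOccupancy(c, rates)
  thetaEq <- c(eq$theta1, eq$theta2)
  d0 <- s - thetaEq
  if (rt <= 1e-10 * abs(tr)) {
    ## defective (or equal-eigenvalue) case: exp(At) d = e^{lt}(d + t (A-lI) d)
    lam <- tr / 2
    Ad <- c(A[1, 1] * d0[1] + A[1, 2] * d0[2],
            A[2, 1] * d0[1] + A[2, 2] * d0[2]) - lam * d0
    e <- exp(lam * tau)
    return(cbind(thetaEq[1] + e * (d0[1] + tau * Ad[1]),
                 thetaEq[2] + e * (d0[2] + tau * Ad[2])))
  }
  vL <- c(lamL + rates@koff2, rates@kon2)
  vS <- c(lamS + rates@koff2, rates@kon2)
  detM <- vL[1] * vS[2] - vS[1] * vL[2]
  alphaL <- (d0[1] * vS[2] - vS[1] * d0[2]) / detM
  alphaS <- (vL[1] * d0[2] - d0[1] * vL[2]) / detM
  eL <- exp(lamL * tau)
  eS <- exp(lamS * tau)
  cbind(thetaEq[1] + alphaL * vL[1] * eL + alphaS * vS[1] * eS,
        thetaEq[2] + alphaL * vL[2] * eL + alphaS * vS[2] * eS)
}

#' Piecewise analytic nested-well solution over an injection schedule
#'
#' Chains the closed-form double-exponential solution across the
#' stepwise titration, with continuity of both occupancies at each
#' injection.  This is the deterministic backbone of the synthetic
#' sensorgram generator and of the joint kinetic fit.
#'
#' @param rates a \code{\link{RateSet}}
#' @param schedule a \code{\link{StepSchedule}}
#' @param times evaluation times, s (non-decreasing, within the schedule)
#' @param theta0 initial state (theta1, theta2) at t = 0
#' @return length(times) x 2 matrix with columns \code{theta1}, \code{theta2}
#' @export
nwSolve <- function(rates, schedule, times, theta0 = c(0, 0)) {
  stopifnot(is(rates, "RateSet"), is(schedule, "StepSchedule"))
  if (any(diff(times) < 0))
    nwStop("evaluation times must be non-decreasing", "nwScheduleError")
  if (any(times < 0) || any(times > schedule@endTime + 1e-9))
    nwStop("evaluation times must lie within the schedule span",
           "nwScheduleError")
  st <- schedule@stepTimes
  cc <- schedule@concentrations
  n <- length(st)
  out <- matrix(NA_real_, length(times), 2,
                dimnames = list(NULL, c("theta1", "theta2")))
  s <- theta0
  for (k in seq_len(n)) {
    tEnd <- if (k < n) st[k + 1] else schedule@endTime
    inStep <- if (k < n) times >= st[k] & times < tEnd else times >= st[k]
    if (any(inStep))
      out[inStep, ] <- stepSolution(s, cc[k], rates, times[inStep] - st[k])
    if (k < n)
      s <- as.numeric(stepSolution(s, cc[k], rates, tEnd - st[k]))
  }
  out
}

#' Numerical-integration oracle for the nested-well rate equations
#'
#' Independently integrates the two-state rate equations across the
#' injection schedule, for verification of the analytic solution.  The
#' default method propagates the exact linear system with the matrix
#' exponential of the augmented (A | b) generator
#' (\code{Matrix::expm}, scaling-and-squaring), which is machine-accurate
#' and shares no code with the eigen-decomposition used by
#' \code{\link{nwSolve}}.  A classical fixed-step fourth-order
#' Runge-Kutta integrator is available as a cross-check.
#'
#' @param rates a \code{\link{RateSet}}
#' @param schedule a \code{\link{StepSchedule}} (piecewise-constant
#'   concentration vs time)
#' @param times evaluation times, s, non-decreasing, within the schedule
#' @param method "expm" (default) or "rk4"
#' @param theta0 initial state at t = 0
#' @return length(times) x 2 matrix with columns \code{theta1}, \code{theta2}
#' @export
odeOracle <- function(rates, schedule, times, method = c("expm", "rk4"),
                      theta0 = c(0, 0)) {
  stopifnot(is(rates, "RateSet"), is(schedule, "StepSchedule"))
  method <- match.arg(method)
  if (any(diff(times) < 0))
    nwStop("evaluation times must be non-decreasing", "nwScheduleError")
  if (any(times < 0) || any(times > schedule@endTime + 1e-9))
    nwStop("evaluation times must lie within the schedule span",
           "nwScheduleError")
  st <- schedule@stepTimes
  cc <- schedule@concentrations
  n <- length(st)
  bounds <- c(st[-1], Inf)

  propagate <- if (method == "expm") {
    function(s, c, dt) {
      if (dt <= 0) return(s)
      rm <- rateMatrix(c, rates)
      G <- rbind(cbind(rm$A, rm$b), c(0, 0, 0))   # augmented generator
      P <- as.matrix(Matrix::expm(G * dt))
      as.numeric(P[1:2, ] %*% c(s, 1))
    }
  } else {
    function(s, c, dt) {
      if (dt <= 0) return(s)
      rm <- rateMatrix(c, rates)
      A <- rm$A; b <- rm$b
      f <- function(y) c(A[1, 1] * y[1] + A[1, 2] * y[2] + b[1],
                         A[2, 1] * y[1] + A[2, 2] * y[2] + b[2])
      normA <- max(abs(A[1, 1]) + abs(A[1, 2]), abs(A[2, 1]) + abs(A[2, 2]))
      nStep <- max(20L, ceiling(dt * normA / 0.02))
      h <- dt / nStep
      y <- s
      for (i in seq_len(nStep)) {
        k1 <- f(y)
        k2 <- f(y + h / 2 * k1)
        k3 <- f(y + h / 2 * k2)
        k4 <- f(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      y
    }
  }

  out <- matrix(NA_real_, length(times), 2,
                dimnames = list(NULL, c("theta1", "theta2")))
  s <- theta0
  tCur <- 0
  kCur <- 1L
  for (i in seq_along(times)) {
    tTarget <- times[i]
    while (kCur < n && tTarget > bounds[kCur]) {
      s <- propagate(s, cc[kCur], bounds[kCur] - tCur)
      tCur <- bounds[kCur]
      kCur <- kCur + 1L
    }
    s <- propagate(s, cc[kCur], tTarget - tCur)
    tCur <- tTarget
    out[i, ] <- s
  }
  out
}
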