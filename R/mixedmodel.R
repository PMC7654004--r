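## Step one of the two-step analysis: pedigree relationship matrix, REML
## variance components for the animal model
##   y = X theta + Z u + W c + e,   u ~ N(0, A su2), c ~ N(0, I sc2),
##   e ~ N(0, I se2),
## Henderson BLUP solutions, and the phenotype pre-adjustment
## y* = y - X theta_hat - W c_hat (breeding-value signal retained).

#' Variance components container
#'
#' @param sigma2_u Additive genetic variance.
#' @param sigma2_c Maternal permanent-environment variance.
#' @param sigma2_e Residual variance.
#' @return List of class `variance_components`.
#' @export
variance_components <- function(sigma2_u, sigma2_c = 0, sigma2_e) {
  if (any(c(sigma2_u, sigma2_c, sigma2_e) < 0))
    stop("variance_components: components must be >= 0", call. = FALSE)
  structure(list(sigma2_u = sigma2_u, sigma2_c = sigma2_c,
                 sigma2_e = sigma2_e),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  r <- variance_ratios(x)
  cat(sprintf(
    "variance components: su2 = %.4g, sc2 = %.4g, se2 = %.4g\n  phenotypic = %.4g, h2 = %.3f, c2 = %.3f\n",
    x$sigma2_u, x$sigma2_c, x$sigma2_e, r$phenotypic, r$h2, r$c2))
  invisible(x)
}

#' Additive relationship matrix by the tabular method
#'
#' Recursion over a parent-before-offspring ordering: founders (and animals
#' with both parents unknown) get diagonal 1; a_ii = 1 + a_sd / 2 when both
#' parents are known; a_ij = (a_j,sire(i) + a_j,dam(i)) / 2 with unknown
#' parents contributing 0. The result is symmetric positive semi-definite.
#'
#' @param pedigree Data frame with columns id, sire, dam (NA = unknown).
#'   Rows are sorted topologically if needed; a cyclic pedigree is an error.
#' @return Dense symmetric matrix with dimnames = ids.
#' @export
build_relationship_matrix <- function(pedigree) {
  ped <- pedigree[, c("id", "sire", "dam")]
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree", call. = FALSE)
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  if (anyNA(s) || anyNA(d))
    stop("pedigree references an unknown id", call. = FALSE)

  ## topological sort (Kahn) if parents do not already precede offspring
  if (any(s >= seq_len(n) & s > 0) || any(d >= seq_len(n) & d > 0)) {
    order_ <- integer(0)
    placed <- logical(n)
    remaining <- seq_len(n)
    repeat {
      ready <- remaining[(s[remaining] == 0L | placed[s[remaining]]) &
                         (d[remaining] == 0L | placed[d[remaining]])]
      if (!length(ready)) {
        if (length(remaining)) stop("cyclic pedigree", call. = FALSE)
        break
      }
      order_ <- c(order_, ready)
      placed[ready] <- TRUE
      remaining <- setdiff(remaining, ready)
      if (!length(remaining)) break
    }
    ped <- ped[order_, ]
    idx <- stats::setNames(seq_len(n), ped$id)
    s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
    d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  }

  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (si > 0) A[j, si] else 0
      row_d <- if (di > 0) A[j, di] else 0
      aij <- 0.5 * (row_s + row_d)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (si > 0 && di > 0) 0.5 * A[si, di] else 0
  }
  A
}

## Shared machinery: P-matrix quantities for V = su2 Gu + sc2 Gc + se2 I.
## Returns Py, y'P Vi P y and tr(P Vi) per component plus the restricted
## log-likelihood.
reml_quadratics <- function(y, X, Glist, sigma2) {
  n <- length(y)
  V <- diag(sigma2[["e"]], n)
  for (nm in names(Glist)) V <- V + sigma2[[nm]] * Glist[[nm]]
  ch <- tryCatch(chol(V), error = function(e)
    stop("reml: V not positive definite", call. = FALSE))
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  chx <- chol(XtVinvX)
  XtVinvX_inv <- chol2inv(chx)
  Py <- drop(Vinv %*% y - VinvX %*% (XtVinvX_inv %*% crossprod(VinvX, y)))
  logl <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y * Py))
  comp <- c(names(Glist), "e")
  ypvpy <- tr_pv <- stats::setNames(numeric(length(comp)), comp)
  GPy <- list()
  for (nm in names(Glist)) {
    Gi <- Glist[[nm]]
    GPy[[nm]] <- drop(Gi %*% Py)
    ypvpy[nm] <- sum(Py * GPy[[nm]])
    B <- crossprod(VinvX, Gi %*% VinvX)        # X'Vinv Gi Vinv X
    tr_pv[nm] <- sum(Vinv * Gi) - sum(XtVinvX_inv * B)
  }
  GPy[["e"]] <- Py
  ypvpy["e"] <- sum(Py * Py)
  tr_pv["e"] <- sum(diag(Vinv)) - sum(XtVinvX_inv * crossprod(VinvX))
  list(Py = Py, GPy = GPy, ypvpy = ypvpy, tr_pv = tr_pv, logl = logl,
       Vinv = Vinv, VinvX = VinvX, XtVinvX_inv = XtVinvX_inv)
}

## apply P to a vector given cached pieces
apply_P <- function(q, v) {
  drop(q$Vinv %*% v - q$VinvX %*% (q$XtVinvX_inv %*% crossprod(q$VinvX, v)))
}

#' REML variance components for the animal model
#'
#' Maximizes the restricted likelihood of (sigma2_u, sigma2_c, sigma2_e) by
#' EM iteration — the exact EM step is
#' `sigma_i^2 <- sigma_i^2 + sigma_i^4 / t_i * (y'P Vi P y - tr(P Vi))`
#' with t_i the dimension of the effect — optionally accelerated by
#' average-information (quasi-Newton) updates with a fallback to EM whenever
#' an AI step leaves the parameter space or decreases the likelihood.
#' Components whose update goes below a small positive floor are pinned
#' there.
#'
#' @param y Trait vector (records).
#' @param X Fixed-effect design matrix, full column rank.
#' @param A Additive relationship matrix over the animals indexed by Z.
#' @param Z Records-by-animals incidence; NULL means one record per animal in
#'   A's order.
#' @param W Records-by-dams incidence for the maternal permanent-environment
#'   term; NULL omits the term.
#' @param init Optional starting `variance_components`.
#' @param tol Relative-change convergence threshold (default 1e-8).
#' @param max_iter Iteration cap (default 500); non-convergence is an error
#'   carrying the trajectory in its condition.
#' @param method "ai" (EM warm-up then average-information) or "em" (pure,
#'   monotone EM).
#' @return `variance_components` with attributes `logl_trajectory`,
#'   `trajectory` (per-iteration components), `iterations`, `converged`.
#' @export
reml_variance_components <- function(y, X, A, Z = NULL, W = NULL,
                                     init = NULL, tol = 1e-8,
                                     max_iter = 500L,
                                     method = c("ai", "em")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (n <= qr(X)$rank)
    stop("reml: need more records than fixed-effect rank", call. = FALSE)
  Gu <- if (is.null(Z)) A else {
    Z <- as.matrix(Z)
    Z %*% A %*% t(Z)
  }
  Glist <- list(u = Gu)
  t_dim <- c(u = if (is.null(Z)) nrow(A) else ncol(Z))
  if (!is.null(W)) {
    W <- as.matrix(W)
    Glist$c <- tcrossprod(W)
    t_dim["c"] <- ncol(W)
  }
  t_dim["e"] <- n

  vy <- stats::var(y)
  floor_ <- 1e-8 * vy
  sigma2 <- if (!is.null(init)) {
    c(u = init$sigma2_u,
      if (!is.null(W)) c(c = init$sigma2_c), e = init$sigma2_e)
  } else {
    s <- c(u = 0.3 * vy, if (!is.null(W)) c(c = 0.1 * vy))
    c(s, e = vy - sum(s))
  }
  names(sigma2) <- c("u", if (!is.null(W)) "c", "e")

  logl_hist <- numeric(0)
  traj <- matrix(NA_real_, nrow = 0, ncol = length(sigma2),
                 dimnames = list(NULL, names(sigma2)))
  em_step <- function(sigma2, q) {
    new <- sigma2 + sigma2^2 / t_dim[names(sigma2)] *
      (q$ypvpy[names(sigma2)] - q$tr_pv[names(sigma2)])
    pmax(new, floor_)
  }
  q <- reml_quadratics(y, X, Glist, sigma2)
  converged <- FALSE
  n_warmup <- if (method == "ai") 3L else max_iter

  for (it in seq_len(max_iter)) {
    logl_hist <- c(logl_hist, q$logl)
    traj <- rbind(traj, sigma2)
    new <- NULL
    q_new <- NULL
    if (it > n_warmup) {
      ## average-information (quasi-Newton) step with step-halving; any
      ## failure falls through to the monotone EM update below
      score_all <- -0.5 * (q$tr_pv[names(sigma2)] - q$ypvpy[names(sigma2)])
      ## active-set update: components sitting at the floor whose gradient
      ## still points outward are held there and dropped from the AI system
      comp <- names(sigma2)[!(sigma2 <= floor_ * 1.001 & score_all < 0)]
      k <- length(comp)
      step <- NULL
      if (k > 0) {
        AI <- matrix(0, k, k, dimnames = list(comp, comp))
        PGPy <- lapply(q$GPy[comp], function(v) apply_P(q, v))
        for (a in seq_len(k)) for (b in a:k) {
          AI[a, b] <- AI[b, a] <- 0.5 *
            sum(q$GPy[[comp[a]]] * PGPy[[comp[b]]])
        }
        step <- tryCatch(drop(solve(AI, score_all[comp])),
                         error = function(e) NULL)
      }
      if (!is.null(step)) {
        full_step <- stats::setNames(numeric(length(sigma2)), names(sigma2))
        full_step[comp] <- step
        for (alpha in c(1, 0.5, 0.25, 0.1)) {
          ## components pushed below the floor are pinned there
          cand <- pmax(sigma2 + alpha * full_step, floor_)
          qc_ <- tryCatch(reml_quadratics(y, X, Glist, cand),
                          error = function(e) NULL)
          if (!is.null(qc_) && qc_$logl >= q$logl - 1e-10) {
            new <- cand
            q_new <- qc_
            break
          }
        }
      }
    }
    if (is.null(new)) {
      new <- em_step(sigma2, q)
      q_new <- reml_quadratics(y, X, Glist, new)
    }
    rel <- abs(new - sigma2) / pmax(abs(sigma2), floor_)
    sigma2 <- new
    q <- q_new
    if (all(rel < tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- errorCondition(
      sprintf("reml: no convergence in %d iterations", max_iter),
      trajectory = traj, logl_trajectory = logl_hist,
      class = "gpcurve_reml_nonconvergence")
    stop(cond)
  }
  out <- variance_components(sigma2[["u"]],
                             if (!is.null(W)) sigma2[["c"]] else 0,
                             sigma2[["e"]])
  attr(out, "logl_trajectory") <- logl_hist
  attr(out, "trajectory") <- traj
  attr(out, "iterations") <- it
  attr(out, "converged") <- TRUE
  out
}

#' Solve Henderson's mixed-model equations
#'
#' Builds and solves the MME with variance ratios lambda_u = se2/su2 on
#' A^-1 and lambda_c = se2/sc2 on I:
#' `[X'X X'Z X'W; Z'X Z'Z + lu A^-1 Z'W; W'X W'Z W'W + lc I] s = [X'y; Z'y; W'y]`.
#'
#' @inheritParams reml_variance_components
#' @param vc `variance_components`; every included term must be strictly
#'   positive.
#' @return List with `theta_hat`, `u_hat`, `c_hat` (NULL if W omitted) and
#'   `mme_residual`, the max-norm of C s - r.
#' @export
blup_solve <- function(y, X, A, vc, Z = NULL, W = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (is.null(Z)) Z <- diag(1, n)
  Z <- as.matrix(Z)
  if (vc$sigma2_u <= 0 || vc$sigma2_e <= 0 ||
      (!is.null(W) && vc$sigma2_c <= 0))
    stop("blup_solve: included variance components must be > 0",
         call. = FALSE)
  lambda_u <- vc$sigma2_e / vc$sigma2_u
  Ainv <- chol2inv(chol(A))
  p <- ncol(X); qu <- ncol(Z)
  blocks <- list(X, Z)
  if (!is.null(W)) {
    W <- as.matrix(W)
    blocks <- c(blocks, list(W))
  }
  M <- do.call(cbind, blocks)
  C <- crossprod(M)
  iu <- p + seq_len(qu)
  C[iu, iu] <- C[iu, iu] + lambda_u * Ainv
  if (!is.null(W)) {
    ic <- p + qu + seq_len(ncol(W))
    C[ic, ic] <- C[ic, ic] + diag(vc$sigma2_e / vc$sigma2_c, ncol(W))
  }
  r <- crossprod(M, y)
  sol <- tryCatch(solve(C, r), error = function(e)
    stop("blup_solve: singular MME coefficient matrix", call. = FALSE))
  sol <- drop(sol)
  out <- list(theta_hat = sol[seq_len(p)],
              u_hat = sol[iu],
              c_hat = if (!is.null(W)) sol[p + qu + seq_len(ncol(W))],
              mme_residual = max(abs(C %*% sol - r)))
  names(out$theta_hat) <- colnames(X)
  if (!is.null(colnames(Z))) names(out$u_hat) <- colnames(Z)
  if (!is.null(W) && !is.null(colnames(W))) names(out$c_hat) <- colnames(W)
  out
}

#' Pre-adjust phenotypes
#'
#' `y* = y - X theta_hat - W c_hat`: estimated fixed and maternal
#' permanent-environment effects are removed while the additive genetic
#' signal is deliberately retained (u_hat is NOT subtracted), so y* is the
#' response for the whole-genome regressions.
#'
#' @param y Trait vector.
#' @param X Fixed-effect design matrix.
#' @param theta_hat Fixed-effect solutions.
#' @param W Maternal incidence matrix (NULL to skip).
#' @param c_hat Maternal solutions (NULL to skip).
#' @return Numeric vector y*.
#' @export
preadjust <- function(y, X, theta_hat, W = NULL, c_hat = NULL) {
  y <- as.numeric(y)
  adj <- y - drop(as.matrix(X) %*% theta_hat)
  if (!is.null(W) && !is.null(c_hat))
    adj <- adj - drop(as.matrix(W) %*% c_hat)
  adj
}

#' Phenotypic variance and variance ratios
#'
#' @param vc `variance_components`.
#' @return List with `phenotypic` (= su2 + sc2 + se2), `h2` (= su2 /
#'   phenotypic) and `c2` (= sc2 / phenotypic).
#' @export
variance_ratios <- function(vc) {
  tot <- vc$sigma2_u + vc$sigma2_c + vc$sigma2_e
  if (tot <= 0) stop("variance_ratios: zero total variance", call. = FALSE)
  list(phenotypic = tot, h2 = vc$sigma2_u / tot, c2 = vc$sigma2_c / tot)
}

#' Build animal-model design matrices from a phenotype table
#'
#' Fixed effects: intercept, sex and contemporary group (reference level of
#' each factor dropped). Z maps records to the pedigree animals carrying
#' breeding values; W maps records to dams with phenotyped offspring.
#'
#' @param phenotypes Data frame with id, sex, contemporary_group, dam_id and
#'   the trait column.
#' @param pedigree Pedigree data frame (id, sire, dam).
#' @param trait Name of the trait column (default "weight").
#' @return List with y, X, Z, W, animal_ids, dam_ids.
#' @export
build_design <- function(phenotypes, pedigree, trait = "weight") {
  y <- phenotypes[[trait]]
  df <- data.frame(sex = factor(phenotypes$sex),
                   cg = factor(phenotypes$contemporary_group))
  keep_terms <- c("1", if (nlevels(df$sex) > 1) "sex",
                  if (nlevels(df$cg) > 1) "cg")
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(keep_terms, collapse = " + "))), df)
  animal_ids <- as.character(pedigree$id)
  Z <- matrix(0, nrow(phenotypes), length(animal_ids),
              dimnames = list(phenotypes$id, animal_ids))
  Z[cbind(seq_len(nrow(phenotypes)),
          match(as.character(phenotypes$id), animal_ids))] <- 1
  dam_ids <- sort(unique(stats::na.omit(as.character(phenotypes$dam_id))))
  W <- NULL
  if (length(dam_ids)) {
    W <- matrix(0, nrow(phenotypes), length(dam_ids),
                dimnames = list(phenotypes$id, dam_ids))
    hit <- !is.na(phenotypes$dam_id)
    W[cbind(which(hit), match(as.character(phenotypes$dam_id[hit]), dam_ids))] <- 1
  }
  list(y = y, X = X, Z = Z, W = W, animal_ids = animal_ids,
       dam_ids = dam_ids)
}

#' Fit the full animal model and pre-adjust the trait
#'
#' Convenience wrapper for step one: builds A and the design matrices, runs
#' REML, solves the MME at the estimates, and returns the pre-adjusted
#' phenotypes alongside the components and solutions.
#'
#' @inheritParams build_design
#' @param tol,max_iter,method Passed to [reml_variance_components()].
#' @return List with `vc`, `ratios`, `solutions`, `y_star` (named by record
#'   id) and the design pieces.
#' @export
fit_animal_model <- function(phenotypes, pedigree, trait = "weight",
                             tol = 1e-8, max_iter = 1000L, method = "ai") {
  ## restrict A to animals that are records or their ancestors
  A <- build_relationship_matrix(pedigree)
  des <- build_design(phenotypes, pedigree, trait)
  vc <- reml_variance_components(des$y, des$X, A, Z = des$Z, W = des$W,
                                 tol = tol, max_iter = max_iter,
                                 method = method)
  sol <- blup_solve(des$y, des$X, A, vc, Z = des$Z, W = des$W)
  y_star <- preadjust(des$y, des$X, sol$theta_hat, des$W, sol$c_hat)
  names(y_star) <- phenotypes$id
  list(vc = vc, ratios = variance_ratios(vc), solutions = sol,
       y_star = y_star, design = des, A = A)
}
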