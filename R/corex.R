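# Discrete latent-factor learning by total correlation explanation.
#
# A layer of M discrete factors Y_1..Y_M (each with `cardinality` states) is
# trained on an n x p matrix of discrete variables by block-coordinate ascent
# on the TC lower bound
#     sum_j [ sum_i alpha_ij I(X_i; Y_j) - H(Y_j) ],
# alternating (i) posterior updates p(y_j | x) given the affinities alpha,
# (ii) re-estimation of the factor marginals p(y_j) and conditionals
# p(x_i | y_j) from the posteriors, and (iii) a softmax competition over
# factors on the model mutual informations I(X_i; Y_j) that concentrates each
# variable's affinity on the factor that explains it best. All information
# quantities are in bits.

as_discrete_matrix <- function(data) {
  if (inherits(data, "discrete_panel")) {
    list(x = data$x, n_levels = data$n_levels)
  } else {
    x <- as.matrix(data)
    if (anyNA(x)) stop("discrete data must not contain missing values")
    if (any(x != round(x)) || any(x < 0)) stop("discrete data must be 0-based integer levels")
    storage.mode(x) <- "integer"
    list(x = x, n_levels = apply(x, 2, max) + 1L)
  }
}

# value indicator matrices D[[v]] (n x p) for v = 0..V-1
value_indicators <- function(x, V) {
  lapply(seq_len(V) - 1L, function(v) {
    d <- (x == v)
    storage.mode(d) <- "double"
    d
  })
}

# scale-free softmax competition across factors on log mutual information
# (equivalently alpha_ij proportional to MI_ij^(1/tau)): what matters is the
# *ratio* of a variable's MI across factors, so a factor with a small but
# leading MI on an otherwise unexplained variable can still win it
softmax_rows <- function(m, tau) {
  lm <- log(m + 1e-12)
  z <- exp((lm - apply(lm, 1, max)) / tau)
  z / rowSums(z)
}

# posterior p(y_j = y | x_s) for every subject and factor, given affinities
# and marginals; returns list over states of n x M matrices plus labels
corex_posterior <- function(D, alpha, model) {
  k <- length(model$log_pxgy)
  V <- length(model$log_pxgy[[1]])
  n <- nrow(D[[1]])
  M <- ncol(alpha)
  logpost <- vector("list", k)
  for (y in seq_len(k)) {
    lp <- matrix(model$log_py[, y], n, M, byrow = TRUE)
    for (v in seq_len(V)) {
      lr <- alpha * (model$log_pxgy[[y]][[v]] - model$log_px[[v]])
      lp <- lp + D[[v]] %*% lr
    }
    logpost[[y]] <- lp
  }
  # normalize across states (log-sum-exp per subject x factor)
  mx <- logpost[[1]]
  for (y in seq_len(k)[-1]) mx <- pmax(mx, logpost[[y]])
  tot <- matrix(0, n, M)
  for (y in seq_len(k)) {
    logpost[[y]] <- exp(logpost[[y]] - mx)
    tot <- tot + logpost[[y]]
  }
  post <- lapply(logpost, function(m) m / tot)
  labels <- matrix(0L, n, M)
  best <- post[[1]]
  for (y in seq_len(k)[-1]) {
    upd <- post[[y]] > best        # strict: ties stay at the lower state
    labels[upd] <- y - 1L
    best[upd] <- post[[y]][upd]
  }
  list(post = post, labels = labels)
}

# marginal re-estimation from posteriors, with add-0.5 pseudocounts
corex_mstep <- function(D, post, n_levels, valid) {
  k <- length(post)
  V <- length(D)
  n <- nrow(D[[1]])
  p <- length(n_levels)
  M <- ncol(post[[1]])
  N_y <- vapply(post, colSums, numeric(M))          # M x k
  if (is.null(dim(N_y))) N_y <- matrix(N_y, nrow = M)
  p_y <- (N_y + 0.5) / (n + 0.5 * k)
  p_y <- p_y / rowSums(p_y)
  log_pxgy <- vector("list", k)
  mi <- matrix(0, p, M)
  # empirical variable marginals (shared across factors)
  log_px <- vector("list", V)
  px <- vector("list", V)
  for (v in seq_len(V)) {
    cnt <- colSums(D[[v]])
    pv <- (cnt + 0.5) / (n + 0.5 * n_levels)
    pv[!valid[, v]] <- NA
    px[[v]] <- pv
    log_px[[v]] <- matrix(ifelse(valid[, v], log(pv), 0), p, M)
  }
  for (y in seq_len(k)) {
    denom <- matrix(N_y[, y], p, M, byrow = TRUE) + 0.5 * n_levels
    log_pxgy[[y]] <- vector("list", V)
    for (v in seq_len(V)) {
      C <- crossprod(D[[v]], post[[y]])             # p x M
      pv <- (C + 0.5) / denom
      lpv <- log(pv)
      lpv[!valid[, v], ] <- 0
      log_pxgy[[y]][[v]] <- lpv
      # MI accumulation: p(y) * p(v|y) * log2(p(v|y)/p(v))
      contrib <- pv * (lpv - log(px[[v]])) / log(2)
      contrib[!valid[, v], ] <- 0
      mi <- mi + contrib * matrix(p_y[, y], p, M, byrow = TRUE)
    }
  }
  mi <- pmax(mi, 0)
  list(log_py = log(p_y), p_y = p_y, log_pxgy = log_pxgy, log_px = log_px,
       mi = mi)
}

corex_objective <- function(alpha, model, post) {
  # TC explained by factor j: sum_i alpha_ij I(X_i;Y_j) - I(X;Y_j), with
  # I(X;Y_j) = H(Y_j) - E_x[H(p(y_j|x))] taken from the current posteriors
  # (subtracting the full H(Y_j) instead would wrongly penalize factors
  # whose posterior is soft)
  M <- ncol(post[[1]])
  k <- length(post)
  p_bar <- vapply(post, colMeans, numeric(M))
  if (is.null(dim(p_bar))) p_bar <- matrix(p_bar, nrow = M)
  h_y <- apply(p_bar, 1, plugin_entropy)
  h_cond <- numeric(M)
  for (y in seq_len(k)) {
    pl <- post[[y]]
    h_cond <- h_cond - colMeans(ifelse(pl > 0, pl * log2(pl), 0))
  }
  i_xy <- pmax(h_y - h_cond, 0)
  tc_j <- colSums(alpha * model$mi) - i_xy
  # `total` is the reported explained TC (factors that explain nothing
  # contribute 0); `raw` is the unclamped bound used to monitor convergence,
  # which keeps moving during the symmetry-breaking burn-in while `total`
  # can sit at 0
  list(tc_j = tc_j, total = sum(pmax(tc_j, 0)), raw = sum(tc_j))
}

#' Fit one layer of discrete latent factors by total correlation explanation
#'
#' @param data A `discrete_panel` from [discretize()] or an integer matrix of
#'   0-based discrete levels (subjects x variables).
#' @param n_factors Number of latent factors M (default 25).
#' @param cardinality Number of states per factor (default 2).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param restarts Number of random initializations; the restart with the
#'   highest explained TC is kept (default 5).
#' @param max_iter Maximum coordinate-ascent iterations per restart.
#' @param tol Convergence tolerance on the explained-TC objective, in bits.
#' @param temperature Softmax temperature of the affinity competition.
#' @param anneal Multiplicative temperature decay factor.
#' @param anneal_every Iterations between temperature decays.
#' @return An object of class `corex_layer` with elements `alpha` (variable x
#'   factor affinities in `[0,1]`, rows summing to 1), `mi` (model mutual
#'   informations in bits), `labels` (per-subject maximum-likelihood state per
#'   factor, 0-based), `posterior`, `explained_tc` (bits per factor, >= 0),
#'   `tc_history` (objective per iteration of the winning restart),
#'   `assignment` (variable -> argmax factor), `converged` flag, and the
#'   marginal estimates needed to label new data.
#' @export
fit_corex <- function(data, n_factors, cardinality = 2L, seed = 1L,
                      restarts = 5L, max_iter = 200L, tol = 1e-6,
                      temperature = 0.1, anneal = 0.9, anneal_every = 10L) {
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (cardinality < 2) stop("cardinality must be >= 2")
  dm <- as_discrete_matrix(data)
  x <- dm$x
  n_levels <- dm$n_levels
  n <- nrow(x); p <- ncol(x); M <- as.integer(n_factors); k <- as.integer(cardinality)
  V <- max(n_levels)
  D <- value_indicators(x, V)
  valid <- outer(n_levels, seq_len(V), function(nl, v) v <= nl)  # p x V

  # one continuous ascent run from a given initialization; alpha is held at
  # `alpha0` during burn-in so factors can differentiate before competition
  train_once <- function(post, alpha0, burn_in) {
    tau <- temperature
    state <- NULL
    prev_total <- -Inf
    prev_raw <- -Inf
    history <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      model <- corex_mstep(D, post, n_levels, valid)
      alpha_new <- if (it <= burn_in) alpha0 else softmax_rows(model$mi, tau)
      es <- corex_posterior(D, alpha_new, model)
      obj <- corex_objective(alpha_new, model, es$post)
      tracked <- it > burn_in + 1L   # trajectory of the competition phase
      if (tracked && obj$total < prev_total - 1e-12) {
        # the update would lower the explained TC: keep the last committed
        # state (ascent has stalled)
        converged <- TRUE
        break
      }
      state <- list(alpha = alpha_new, model = model, post = es$post,
                    labels = es$labels, obj = obj)
      if (tracked) history <- c(history, obj$total)
      if (tracked && is.finite(prev_raw) && abs(obj$raw - prev_raw) < tol) {
        converged <- TRUE
        break
      }
      if (tracked) {
        prev_total <- obj$total
        prev_raw <- obj$raw
      }
      post <- es$post
      if (it > burn_in && it %% anneal_every == 0) tau <- tau * anneal
    }
    state$converged <- converged
    state$history <- history
    state
  }

  # anchor a factor's posterior to one child variable: state = child value
  # mapped onto 0..k-1 (with light smoothing), planting the asymmetric
  # "copy one child" solution that EM often misses for weakly dependent
  # children (the symmetric mixture is a local optimum with negative TC)
  anchor_posterior <- function(post, dj, child) {
    v <- x[, child]
    V_c <- n_levels[child]
    state <- if (V_c <= 1) rep(0L, n) else round(v * (k - 1) / (V_c - 1))
    for (y in seq_len(k)) post[[y]][, dj] <- ifelse(state == y - 1L, 0.95, 0.05 / (k - 1))
    post
  }

  # dead factors (explaining essentially nothing) are re-anchored: one that
  # still holds variables is anchored to its most informative child; one with
  # none grabs the worst-explained half of the most overloaded factor and is
  # anchored to the grabbed child with the highest entropy. The warm restart
  # is kept only if it improves the explained TC.
  reseed_init <- function(st) {
    dead <- which(st$obj$tc_j < 0.01)
    if (!length(dead)) return(NULL)
    assign <- max.col(st$alpha, ties.method = "first")
    counts <- tabulate(assign, M)
    alpha0 <- matrix(0, p, M)
    alpha0[cbind(seq_len(p), assign)] <- 1
    post <- st$post
    h_x <- vapply(seq_len(p), function(i) {
      plugin_entropy(tabulate(x[, i] + 1L, n_levels[i]))
    }, numeric(1))
    taken <- rep(FALSE, p)
    changed <- FALSE
    # dead factors that still hold variables first (they keep them, anchored
    # to their best child); empty dead factors then grab from donors
    dead <- dead[order(-counts[dead])]
    for (dj in dead) {
      vars <- setdiff(which(assign == dj), which(taken))
      grabbed <- FALSE
      if (!length(vars)) {
        donors <- order(-counts)
        donors <- setdiff(donors[counts[donors] >= 4], dj)
        live <- setdiff(donors, dead)
        tgt <- if (length(live)) live[1] else if (length(donors)) donors[1] else NA
        if (is.na(tgt)) next
        cand <- setdiff(which(assign == tgt), which(taken))
        if (length(cand) < 2) next
        vars <- cand[order(st$model$mi[cbind(cand, tgt)])]
        vars <- vars[seq_len(max(2L, floor(length(cand) / 2)))]
        counts[tgt] <- counts[tgt] - length(vars)
        alpha0[vars, ] <- 0
        alpha0[vars, dj] <- 1
        grabbed <- TRUE
      }
      mi_v <- st$model$mi[cbind(vars, dj)]
      anchor <- if (!grabbed && any(mi_v > 0)) {
        vars[which.max(mi_v)]
      } else {
        vars[which.max(h_x[vars])]
      }
      post <- anchor_posterior(post, dj, anchor)
      taken[vars] <- TRUE
      changed <- TRUE
    }
    if (!changed) return(NULL)
    list(post = post, alpha0 = alpha0)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(as.integer(seed) + (r - 1L) * 1009L)
    post <- lapply(seq_len(k), function(y) matrix(stats::rexp(n * M), n, M))
    tot0 <- Reduce(`+`, post)
    post <- lapply(post, function(m) m / tot0)
    # hard random variable -> factor assignment to break factor symmetry
    alpha0 <- matrix(0, p, M)
    alpha0[cbind(seq_len(p), sample.int(M, p, replace = TRUE))] <- 1
    st <- train_once(post, alpha0, burn_in = 15L)
    for (round in 1:3) {
      init <- reseed_init(st)
      if (is.null(init)) break
      cand <- train_once(init$post, init$alpha0, burn_in = 5L)
      if (cand$obj$total > st$obj$total + 1e-9) st <- cand else break
    }
    if (is.null(best) || st$obj$total > best$obj$total) {
      best <- st
      best$restart <- r
    }
  }
  if (!best$converged) {
    warning("fit_corex did not converge within max_iter; returning best iterate")
  }
  # canonicalize the (otherwise arbitrary) state order of each factor so the
  # 0..k-1 labels are monotone along the factor's own variable direction:
  # states are sorted by the posterior-weighted mean of a sign-aligned,
  # affinity-weighted sum of the (standardized) member variables, making the
  # labels usable as ordinal numerics downstream
  xs <- scale(x)
  xs[is.nan(xs)] <- 0
  for (j in seq_len(M)) {
    anchor <- which.max(best$alpha[, j])
    sgn <- sign(stats::cov(x, x[, anchor]))
    sgn[sgn == 0] <- 1
    score <- as.vector(xs %*% (best$alpha[, j] * sgn))
    state_mean <- vapply(seq_len(k), function(y) {
      w <- best$post[[y]][, j]
      sum(w * score) / sum(w)
    }, numeric(1))
    perm <- order(state_mean)
    if (!identical(perm, seq_len(k))) {
      best$post <- local({
        p0 <- best$post
        for (y in seq_len(k)) p0[[y]][, j] <- best$post[[perm[y]]][, j]
        p0
      })
      best$model$p_y[j, ] <- best$model$p_y[j, perm]
      best$model$log_py[j, ] <- best$model$log_py[j, perm]
      lx <- best$model$log_pxgy
      for (y in seq_len(k)) {
        for (v in seq_along(lx[[y]])) {
          best$model$log_pxgy[[y]][[v]][, j] <- lx[[perm[y]]][[v]][, j]
        }
      }
      remap <- integer(k)
      remap[perm] <- seq_len(k)
      best$labels[, j] <- remap[best$labels[, j] + 1L] - 1L
    }
  }
  alpha <- best$alpha
  dimnames(alpha) <- list(colnames(x), sprintf("F%02d", seq_len(M) - 1L))
  structure(list(
    alpha = alpha,
    mi = best$model$mi,
    labels = best$labels,
    posterior = best$post,
    explained_tc = pmax(best$obj$tc_j, 0),
    tc_history = best$history,
    assignment = stats::setNames(max.col(alpha, ties.method = "first"), colnames(x)),
    p_y = best$model$p_y,
    model = best$model,
    converged = best$converged,
    restart = best$restart,
    config = list(n_factors = M, cardinality = k, seed = as.integer(seed),
                  restarts = as.integer(restarts), max_iter = as.integer(max_iter),
                  tol = tol, temperature = temperature, anneal = anneal,
                  anneal_every = as.integer(anneal_every)),
    n_levels = n_levels,
    variables = colnames(x)
  ), class = "corex_layer")
}

#' @export
print.corex_layer <- function(x, ...) {
  cat(sprintf("<corex_layer> %d factors (k=%d) over %d variables; explained TC %.3f bits%s\n",
              x$config$n_factors, x$config$cardinality, length(x$variables),
              sum(x$explained_tc),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Maximum-likelihood factor labels for (new) subjects
#'
#' Computes the per-subject posterior over states for every factor of a
#' trained layer and returns the maximum-likelihood state labels (ties broken
#' toward the lowest state index) as a `feature_table` tagged `corex_plasma`
#' or `corex_brain`.
#'
#' @param layer A trained `corex_layer`.
#' @param data Discrete data with the training variables: a
#'   `discrete_panel`, integer matrix, or `NULL` to return the training
#'   labels.
#' @param panel Which panel the input variables came from (`"plasma"` or
#'   `"brain"`); sets the class tag and column prefix (`corexP_` / `corexB_`).
#' @param subjects Optional subject IDs (defaults to the data rownames).
#' @return A `feature_table` of factor label columns (0-based states).
#' @export
factor_labels <- function(layer, data = NULL, panel = c("plasma", "brain"),
                          subjects = NULL) {
  panel <- match.arg(panel)
  prefix <- if (panel == "plasma") "corexP" else "corexB"
  tag <- if (panel == "plasma") "corex_plasma" else "corex_brain"
  if (is.null(data)) {
    labels <- layer$labels
  } else {
    dm <- as_discrete_matrix(data)
    if (ncol(dm$x) != length(layer$variables)) {
      stop(sprintf("data has %d variables but the layer was trained on %d",
                   ncol(dm$x), length(layer$variables)))
    }
    V <- length(layer$model$log_px)
    D <- value_indicators(dm$x, V)
    labels <- corex_posterior(D, layer$alpha, layer$model)$labels
    if (is.null(subjects) && !is.null(rownames(dm$x))) subjects <- rownames(dm$x)
  }
  M <- layer$config$n_factors
  colnames(labels) <- sprintf("%s_%02d", prefix, seq_len(M) - 1L)
  if (!is.null(subjects)) rownames(labels) <- subjects
  if (is.null(rownames(labels))) rownames(labels) <- sprintf("S%04d", seq_len(nrow(labels)))
  feature_table(labels, stats::setNames(rep(tag, M), colnames(labels)))
}

#' Serialize a trained factor layer to JSON
#'
#' Writes affinities, marginal estimates, explained TC, configuration and
#' seed; [corex_from_json()] restores an equivalent layer able to label new
#' data.
#'
#' @param layer A `corex_layer`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
corex_to_json <- function(layer, path) {
  # all matrices are stored as flat column-major vectors with known dims so
  # the reader is immune to JSON array-simplification ambiguity
  payload <- list(
    variables = layer$variables,
    n_levels = layer$n_levels,
    alpha = as.vector(layer$alpha),
    mi = as.vector(layer$mi),
    p_y = as.vector(layer$p_y),
    log_py = as.vector(layer$model$log_py),
    log_pxgy = lapply(layer$model$log_pxgy, function(st) lapply(st, as.vector)),
    log_px = lapply(layer$model$log_px, as.vector),
    explained_tc = layer$explained_tc,
    converged = layer$converged,
    config = layer$config
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a factor layer from JSON
#' @param path File written by [corex_to_json()].
#' @return A `corex_layer` (without training posteriors/history).
#' @export
corex_from_json <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = FALSE)
  pl$variables <- unlist(pl$variables)
  pl$config <- lapply(pl$config, function(v) if (is.list(v)) unlist(v) else v)
  M <- pl$config$n_factors
  p <- length(pl$variables)
  k <- pl$config$cardinality
  as_pm <- function(m) matrix(as.numeric(unlist(m)), p, M)
  model <- list(
    log_py = matrix(as.numeric(unlist(pl$log_py)), M, k),
    p_y = matrix(as.numeric(unlist(pl$p_y)), M, k),
    log_pxgy = lapply(seq_len(k), function(y) lapply(pl$log_pxgy[[y]], as_pm)),
    log_px = lapply(pl$log_px, as_pm),
    mi = as_pm(pl$mi)
  )
  alpha <- as_pm(pl$alpha)
  dimnames(alpha) <- list(pl$variables, sprintf("F%02d", seq_len(M) - 1L))
  structure(list(
    alpha = alpha, mi = model$mi, labels = NULL, posterior = NULL,
    explained_tc = as.numeric(unlist(pl$explained_tc)), tc_history = NULL,
    assignment = stats::setNames(max.col(alpha, ties.method = "first"), pl$variables),
    p_y = model$p_y, model = model, converged = isTRUE(pl$converged),
    config = pl$config, n_levels = as.integer(unlist(pl$n_levels)),
    variables = pl$variables
  ), class = "corex_layer")
}

# plug-in MI (bits) between every column of a small-alphabet discrete matrix
# and every column of a discrete label matrix, via joint-count cross-products
empirical_mi_matrix <- function(x, labels) {
  dx <- as_discrete_matrix(x); dl <- as_discrete_matrix(labels)
  n <- nrow(dx$x)
  Vx <- max(dx$n_levels); Vl <- max(dl$n_levels)
  Dx <- value_indicators(dx$x, Vx)
  Dl <- value_indicators(dl$x, Vl)
  p <- ncol(dx$x); M <- ncol(dl$x)
  mi <- matrix(0, p, M, dimnames = list(colnames(dx$x), colnames(dl$x)))
  px <- lapply(Dx, colSums)   # counts
  pl <- lapply(Dl, colSums)
  for (v in seq_len(Vx)) {
    for (u in seq_len(Vl)) {
      J <- crossprod(Dx[[v]], Dl[[u]])  # p x M joint counts
      denom <- outer(px[[v]], pl[[u]])
      term <- (J / n) * log2((J * n) / denom)
      term[J == 0 | denom == 0] <- 0
      mi <- mi + term
    }
  }
  pmax(mi, 0)
}
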