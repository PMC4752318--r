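# Neighborhood regularized logistic matrix factorization.
#
# Each drug i and target j carries an r-dimensional latent vector (rows of
# U and V); the interaction probability is the logistic of their inner
# product. Known interactions count c-fold in the likelihood; Gaussian
# priors (precision lambda_d, lambda_t) and kNN graph Laplacian penalties
# (weights alpha, beta) regularize the latents. Training minimizes
#
#   sum_ij (1 + c y_ij - y_ij) ln(1 + exp(u_i v_j')) - c y_ij u_i v_j'
#     + 1/2 tr(U' (lambda_d I + alpha L_d) U)
#     + 1/2 tr(V' (lambda_t I + beta  L_t) V)
#
# by alternating AdaGrad sweeps. At prediction time the latent vector of an
# entity with no training interactions is replaced by the similarity-weighted
# mean of its K2 nearest neighbors that do have interactions (cold-start
# smoothing).

#' Hyperparameters for an NRLMF model
#'
#' @param c importance weight of observed interactions (>= 1); an observed
#'   pair counts as `c` positive examples, an unknown pair as one negative.
#' @param r latent dimensionality.
#' @param K1 neighborhood size of the training-time Laplacian regularizers.
#' @param K2 neighborhood size of the prediction-time cold-start smoothing.
#' @param lambda_d,lambda_t Gaussian prior precisions (1 / variance) on drug
#'   and target latent vectors.
#' @param alpha,beta weights of the drug and target neighborhood penalties.
#' @param gamma AdaGrad base learning rate.
#' @param max_iter number of alternating sweeps; there is no early stopping,
#'   inspect the objective trace for convergence.
#' @param seed integer seed for the Gaussian initialization.
#' @return a list of class `nrlmf_hyperparams`.
#' @export
nrlmf_hyperparams <- function(c = 5, r = 50, K1 = 5, K2 = 5,
                              lambda_d = 0.5, lambda_t = 0.5,
                              alpha = 1, beta = 1,
                              gamma = 0.5, max_iter = 100, seed = 1L) {
  hp <- list(c = c, r = as.integer(r), K1 = as.integer(K1), K2 = as.integer(K2),
             lambda_d = lambda_d, lambda_t = lambda_t,
             alpha = alpha, beta = beta, gamma = gamma,
             max_iter = as.integer(max_iter), seed = as.integer(seed))
  if (hp$c < 1) stop_validation("c must be >= 1 (got %g)", hp$c)
  if (hp$r < 1) stop_validation("r must be >= 1")
  if (hp$K1 < 0 || hp$K2 < 0) stop_validation("K1 and K2 must be nonnegative")
  if (hp$lambda_d <= 0 || hp$lambda_t <= 0) stop_validation("lambda_d and lambda_t must be > 0")
  if (hp$alpha < 0 || hp$beta < 0) stop_validation("alpha and beta must be nonnegative")
  if (hp$gamma <= 0) stop_validation("gamma must be > 0")
  if (hp$max_iter < 1) stop_validation("max_iter must be >= 1")
  structure(hp, class = "nrlmf_hyperparams")
}

#' Default hyperparameter grid for grid search
#'
#' The grid conventionally searched for this model: shared prior precision
#' `lambda` in `2^(-5..1)`, `alpha` in `2^(-5..2)`, `beta` in `2^(-5..0)`,
#' learning rate `gamma` in `2^(-3..0)` and latent dimension `r` in
#' `{50, 100}`.
#'
#' @return a named list of value vectors suitable for [grid_search_nrlmf()].
#' @export
default_grid <- function() {
  list(
    lambda = 2^(-5:1),
    alpha = 2^(-5:2),
    beta = 2^(-5:0),
    gamma = 2^(-3:0),
    r = c(50L, 100L)
  )
}

#' Logistic interaction probabilities
#'
#' `P = logistic(U V')` elementwise, evaluated overflow-safely.
#'
#' @param U drug latent matrix `[m x r]`.
#' @param V target latent matrix `[n x r]`.
#' @return matrix `[m x n]` of probabilities in (0, 1).
#' @export
interaction_probability <- function(U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (ncol(U) != ncol(V)) {
    stop_validation("latent dimensions differ: U has %d columns, V has %d",
                    ncol(U), ncol(V))
  }
  P <- stats::plogis(tcrossprod(U, V))
  # keep the open interval: plogis saturates to exactly 1 near +/-700
  pmin(pmax(P, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' NRLMF objective value
#'
#' The regularized negative log-posterior minimized during training. With
#' `alpha = beta = 0` it reduces to plain weighted logistic matrix
#' factorization with spherical Gaussian priors.
#'
#' @param U,V latent matrices.
#' @param Y binary interaction matrix.
#' @param hyper an `nrlmf_hyperparams`.
#' @param Ld,Lt Laplacian matrices (or `laplacian_pair`s); may be `NULL`
#'   when the corresponding weight is zero.
#' @return scalar objective value.
#' @export
nrlmf_objective <- function(U, V, Y, hyper, Ld = NULL, Lt = NULL) {
  if (inherits(Ld, "laplacian_pair")) Ld <- Ld$L
  if (inherits(Lt, "laplacian_pair")) Lt <- Lt$L
  X <- tcrossprod(U, V)
  W <- 1 + hyper$c * Y - Y
  val <- sum(W * log1pexp(X) - hyper$c * Y * X) +
    0.5 * hyper$lambda_d * sum(U^2) + 0.5 * hyper$lambda_t * sum(V^2)
  if (hyper$alpha > 0) {
    if (is.null(Ld)) stop_validation("alpha > 0 requires the drug Laplacian")
    val <- val + 0.5 * hyper$alpha * sum(U * (Ld %*% U))
  }
  if (hyper$beta > 0) {
    if (is.null(Lt)) stop_validation("beta > 0 requires the target Laplacian")
    val <- val + 0.5 * hyper$beta * sum(V * (Lt %*% V))
  }
  val
}

#' Analytic gradients of the NRLMF objective
#'
#' `dL/dU = (P + (c-1) Y*P - c Y) V + (lambda_d I + alpha L_d) U` and
#' symmetrically for `V`, with `P` the logistic probability matrix and `*`
#' the elementwise product.
#'
#' @inheritParams nrlmf_objective
#' @return list with matrices `Gd` `[m x r]` and `Gt` `[n x r]`.
#' @export
nrlmf_gradients <- function(U, V, Y, hyper, Ld = NULL, Lt = NULL) {
  if (inherits(Ld, "laplacian_pair")) Ld <- Ld$L
  if (inherits(Lt, "laplacian_pair")) Lt <- Lt$L
  P <- interaction_probability(U, V)
  M <- P + (hyper$c - 1) * (Y * P) - hyper$c * Y
  Gd <- M %*% V + hyper$lambda_d * U
  Gt <- crossprod(M, U) + hyper$lambda_t * V
  if (hyper$alpha > 0) Gd <- Gd + hyper$alpha * (Ld %*% U)
  if (hyper$beta > 0) Gt <- Gt + hyper$beta * (Lt %*% V)
  list(Gd = Gd, Gt = Gt)
}

#' Random Gaussian initialization of the latent matrices
#'
#' Entries i.i.d. normal with mean 0 and standard deviation `1 / sqrt(r)`,
#' so initial inner products have unit-order variance regardless of `r`.
#'
#' @param m,n numbers of drugs and targets.
#' @param r latent dimensionality.
#' @param seed integer seed; the draw is reproducible.
#' @return list with matrices `U` `[m x r]` and `V` `[n x r]`.
#' @export
initialize_latents <- function(m, n, r, seed) {
  if (m < 1 || n < 1 || r < 1) stop_validation("dimensions must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sd0 <- 1 / sqrt(r)
  list(U = matrix(stats::rnorm(m * r, 0, sd0), m, r),
       V = matrix(stats::rnorm(n * r, 0, sd0), n, r))
}

#' Fit an NRLMF model
#'
#' Builds the kNN Laplacians from the dataset's similarity matrices, draws
#' the Gaussian initialization, and runs `max_iter` alternating AdaGrad
#' sweeps: the full gradient in `U` is computed with `V` fixed, squared
#' gradients accumulate elementwise into `phi`, and each coordinate moves by
#' `-gamma * g / sqrt(phi)` (a coordinate whose accumulated `phi` is zero
#' moves by zero); then symmetrically for `V`. Cold-start smoothed latents
#' are computed from the training positive sets and stored on the model.
#'
#' @param ds a `dti_dataset` (its `Y` is the training matrix).
#' @param hyper an [nrlmf_hyperparams()].
#' @return an object of class `nrlmf` with fields `U`, `V`, `U_smooth`,
#'   `V_smooth`, `pos` (training positive sets), `hyper`, `objective_trace`,
#'   `drug_ids`, `target_ids`.
#' @export
nrlmf <- function(ds, hyper = nrlmf_hyperparams()) {
  stopifnot(inherits(ds, "dti_dataset"))
  Y <- ds$Y
  m <- nrow(Y); n <- ncol(Y); r <- hyper$r

  Ld <- build_laplacian(build_adjacency(ds$Sd, hyper$K1))$L
  Lt <- build_laplacian(build_adjacency(ds$St, hyper$K1))$L

  init <- initialize_latents(m, n, r, hyper$seed)
  U <- init$U; V <- init$V
  phi <- matrix(0, m, r)
  psi <- matrix(0, n, r)
  trace <- numeric(hyper$max_iter + 1L)
  trace[1] <- nrlmf_objective(U, V, Y, hyper, Ld, Lt)

  adagrad_step <- function(G, acc, gamma) {
    acc <- acc + G * G
    step <- matrix(0, nrow(G), ncol(G))
    nz <- acc > 0
    step[nz] <- gamma * G[nz] / sqrt(acc[nz])
    list(step = step, acc = acc)
  }

  for (it in seq_len(hyper$max_iter)) {
    Gd <- nrlmf_gradients(U, V, Y, hyper, Ld, Lt)$Gd
    upd <- adagrad_step(Gd, phi, hyper$gamma)
    phi <- upd$acc
    U <- U - upd$step

    Gt <- nrlmf_gradients(U, V, Y, hyper, Ld, Lt)$Gt
    upd <- adagrad_step(Gt, psi, hyper$gamma)
    psi <- upd$acc
    V <- V - upd$step

    trace[it + 1L] <- nrlmf_objective(U, V, Y, hyper, Ld, Lt)
    if (!is.finite(trace[it + 1L])) {
      stop_divergence(
        "objective became non-finite at iteration %d; try a smaller gamma (current %g)",
        it, hyper$gamma)
    }
  }

  pos <- positive_sets(Y)
  model <- structure(
    list(U = U, V = V, pos = pos, hyper = hyper,
         Sd = ds$Sd, St = ds$St,
         drug_ids = ds$drug_ids, target_ids = ds$target_ids,
         objective_trace = trace),
    class = "nrlmf")
  sm <- smooth_latents(model)
  model$U_smooth <- sm$U
  model$V_smooth <- sm$V
  model
}

#' @export
print.nrlmf <- function(x, ...) {
  cat(sprintf("<nrlmf> %d drugs x %d targets, r = %d, %d iterations\n",
              nrow(x$U), nrow(x$V), x$hyper$r, x$hyper$max_iter))
  cat(sprintf("  objective: %.4f -> %.4f\n",
              x$objective_trace[1], x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

# Smooth one latent matrix: rows in `positive` pass through; each other row
# becomes the similarity-weighted mean of its K2 most similar positive rows
# (ties by ascending index; fewer than K2 positives means all of them).
smooth_matrix <- function(M, S, positive, K2, what) {
  m <- nrow(M)
  out <- M
  negative <- setdiff(seq_len(m), positive)
  if (length(negative) == 0) return(out)
  if (length(positive) == 0) {
    warning(sprintf("no %s with known interactions; smoothed vectors are zero", what))
    out[negative, ] <- 0
    return(out)
  }
  for (i in negative) {
    k_eff <- min(K2, length(positive))
    if (k_eff == 0) {
      out[i, ] <- 0
      next
    }
    ord <- positive[order(-S[i, positive], positive)]
    nb <- ord[seq_len(k_eff)]
    w <- S[i, nb]
    tot <- sum(w)
    if (tot == 0) {
      warning(sprintf("%s %d has only zero-similarity positive neighbors; smoothed vector set to zero",
                      what, i))
      out[i, ] <- 0
    } else {
      out[i, ] <- as.numeric(crossprod(w / tot, M[nb, , drop = FALSE]))
    }
  }
  out
}

#' Cold-start smoothing of the learned latent vectors
#'
#' Latent vectors of drugs/targets with at least one training interaction
#' pass through unchanged. A drug with none (a "new" drug) gets the
#' similarity-weighted mean of the latent vectors of its `K2` most similar
#' drugs that do have interactions, weights normalized to sum to one;
#' symmetrically for targets. If every selected neighbor has similarity
#' zero the smoothed vector is zero, with a warning.
#'
#' @param model a fitted `nrlmf` object.
#' @return list with smoothed matrices `U` and `V`.
#' @export
smooth_latents <- function(model) {
  stopifnot(inherits(model, "nrlmf"))
  list(
    U = smooth_matrix(model$U, model$Sd, model$pos$positive_drugs,
                      model$hyper$K2, "drug"),
    V = smooth_matrix(model$V, model$St, model$pos$positive_targets,
                      model$hyper$K2, "target")
  )
}

#' Predict interaction probabilities from a fitted model
#'
#' The logistic of the inner products of the cold-start smoothed latent
#' vectors. For drugs and targets that had training interactions this is
#' identical to the training-time probability.
#'
#' @param object a fitted `nrlmf` model.
#' @param drug,target optional indices (or id strings); when both are given
#'   a single probability is returned, otherwise the full `[m x n]`
#'   probability matrix.
#' @param ... unused.
#' @return a probability matrix with drug/target `dimnames`, or a scalar.
#' @export
predict.nrlmf <- function(object, drug = NULL, target = NULL, ...) {
  resolve <- function(idx, ids, what) {
    if (is.character(idx)) {
      pos <- match(idx, ids)
      if (anyNA(pos)) stop_validation("unknown %s id '%s'", what, idx[is.na(pos)][1])
      pos
    } else {
      idx <- as.integer(idx)
      if (any(idx < 1 | idx > length(ids))) {
        stop_validation("%s index out of range 1..%d", what, length(ids))
      }
      idx
    }
  }
  if (is.null(drug) != is.null(target)) {
    stop_validation("provide both drug and target, or neither")
  }
  if (is.null(drug)) {
    P <- interaction_probability(object$U_smooth, object$V_smooth)
    dimnames(P) <- list(object$drug_ids, object$target_ids)
    return(P)
  }
  i <- resolve(drug, object$drug_ids, "drug")
  j <- resolve(target, object$target_ids, "target")
  stats::plogis(rowSums(object$U_smooth[i, , drop = FALSE] *
                          object$V_smooth[j, , drop = FALSE]))
}

#' Serialize a fitted model to a directory of text files
#'
#' Writes `U.tsv`, `V.tsv`, the smoothed counterparts and a flat key-value
#' `metadata.tsv` with the hyperparameters and seed — enough to reload with
#' [read_nrlmf_model()] and predict bit-identically.
#'
#' @param model a fitted `nrlmf`.
#' @param dir directory to create/fill.
#' @return `dir`, invisibly.
#' @export
write_nrlmf_model <- function(model, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop_io("cannot create model directory '%s'", dir)
  }
  lab <- function(M, rn) {
    dimnames(M) <- list(rn, paste0("k", seq_len(ncol(M))))
    M
  }
  write_labeled_matrix(lab(model$U, model$drug_ids), file.path(dir, "U.tsv"))
  write_labeled_matrix(lab(model$V, model$target_ids), file.path(dir, "V.tsv"))
  write_labeled_matrix(lab(model$U_smooth, model$drug_ids), file.path(dir, "U_smooth.tsv"))
  write_labeled_matrix(lab(model$V_smooth, model$target_ids), file.path(dir, "V_smooth.tsv"))
  hp <- model$hyper
  meta <- c(vapply(names(unclass(hp)), function(k) {
    sprintf("%s\t%s", k, format_num(hp[[k]]))
  }, character(1)),
  sprintf("positive_drugs\t%s", paste(model$pos$positive_drugs, collapse = ",")),
  sprintf("positive_targets\t%s", paste(model$pos$positive_targets, collapse = ",")))
  writeLines(meta, file.path(dir, "metadata.tsv"), useBytes = TRUE)
  writeLines(format_num(model$objective_trace), file.path(dir, "objective_trace.txt"))
  invisible(dir)
}

#' Reload a model serialized by [write_nrlmf_model()]
#'
#' @param dir model directory.
#' @return an `nrlmf` object whose predictions match the original exactly.
#' @export
read_nrlmf_model <- function(dir) {
  need <- file.path(dir, c("U.tsv", "V.tsv", "U_smooth.tsv", "V_smooth.tsv", "metadata.tsv"))
  if (!all(file.exists(need))) stop_io("'%s' is not a serialized model directory", dir)
  U <- read_labeled_matrix(need[1])
  V <- read_labeled_matrix(need[2])
  Us <- read_labeled_matrix(need[3])
  Vs <- read_labeled_matrix(need[4])
  kv <- utils::read.delim(need[5], header = FALSE, colClasses = "character")
  meta <- stats::setNames(kv[[2]], kv[[1]])
  num <- function(k) as.numeric(meta[[k]])
  idx <- function(k) {
    if (!nzchar(meta[[k]])) integer(0) else as.integer(strsplit(meta[[k]], ",")[[1]])
  }
  hyper <- nrlmf_hyperparams(
    c = num("c"), r = num("r"), K1 = num("K1"), K2 = num("K2"),
    lambda_d = num("lambda_d"), lambda_t = num("lambda_t"),
    alpha = num("alpha"), beta = num("beta"), gamma = num("gamma"),
    max_iter = num("max_iter"), seed = num("seed"))
  trace_path <- file.path(dir, "objective_trace.txt")
  trace <- if (file.exists(trace_path)) as.numeric(readLines(trace_path)) else numeric(0)
  pos_d <- idx("positive_drugs"); pos_t <- idx("positive_targets")
  structure(
    list(U = unname(U), V = unname(V),
         pos = list(positive_drugs = pos_d,
                    negative_drugs = setdiff(seq_len(nrow(U)), pos_d),
                    positive_targets = pos_t,
                    negative_targets = setdiff(seq_len(nrow(V)), pos_t)),
         hyper = hyper, Sd = NULL, St = NULL,
         drug_ids = rownames(U), target_ids = rownames(V),
         objective_trace = trace,
         U_smooth = unname(Us), V_smooth = unname(Vs)),
    class = "nrlmf")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the latent factors of a fitted model
#'
#' One row per entity per latent dimension, suitable for plotting or
#' joining with annotation.
#'
#' @param x a fitted `nrlmf`.
#' @param ... unused.
#' @return tibble with columns `entity` (drug/target), `id`, `dimension`,
#'   `value`, `smoothed`.
#' @method tidy nrlmf
#' @export
tidy.nrlmf <- function(x, ...) {
  one <- function(M, ids, entity, smoothed) {
    tibble::tibble(
      entity = entity,
      id = rep(ids, times = ncol(M)),
      dimension = rep(seq_len(ncol(M)), each = nrow(M)),
      value = as.numeric(M),
      smoothed = smoothed)
  }
  dplyr::bind_rows(
    one(x$U, x$drug_ids, "drug", FALSE),
    one(x$V, x$target_ids, "target", FALSE),
    one(x$U_smooth, x$drug_ids, "drug", TRUE),
    one(x$V_smooth, x$target_ids, "target", TRUE))
}

#' One-row model summary
#'
#' @param x a fitted `nrlmf`.
#' @param ... unused.
#' @return tibble with dimensions, final/initial objective and key
#'   hyperparameters.
#' @method glance nrlmf
#' @export
glance.nrlmf <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x$U), n_targets = nrow(x$V), r = x$hyper$r,
    c = x$hyper$c, K1 = x$hyper$K1, K2 = x$hyper$K2,
    objective_initial = x$objective_trace[1],
    objective_final = x$objective_trace[length(x$objective_trace)],
    iterations = x$hyper$max_iter)
}
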