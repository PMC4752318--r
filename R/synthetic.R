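# Benchmark-shaped synthetic datasets with planted low-rank structure.
#
# Ground-truth latents U*, V* are Gaussian; interactions are Bernoulli draws
# of logistic(U* V*' + b), where the intercept b is solved so the mean
# planted probability matches a requested interaction density (without it, a
# symmetric zero-mean inner-product distribution pins the expected density
# at one half). Similarities are a Gaussian kernel on the same latent
# geometry, so the neighborhood-smoothness assumption of the model genuinely
# holds and recovery experiments are meaningful; an independent-random
# similarity variant exercises robustness paths.

# Gaussian kernel similarity with the median-heuristic bandwidth:
# S[i,mu] = exp(-||x_i - x_mu||^2 / (2 h^2)), h = median pairwise distance.
latent_similarity <- function(X) {
  d2 <- as.matrix(stats::dist(X))^2
  h2 <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(h2) || h2 == 0) h2 <- 1
  S <- exp(-d2 / (2 * h2))
  diag(S) <- 1
  S
}

#' Generate a planted low-rank interaction dataset
#'
#' Draws ground-truth latents with i.i.d. normal(0, `scale / sqrt(r_true)`)
#' entries, computes planted probabilities `P* = logistic(U* V*' + b)` with
#' the intercept `b` solved so that `mean(P*)` equals `density`, and samples
#' `Y` Bernoulli from `P*`. Similarities are a median-bandwidth Gaussian
#' kernel on the latent rows (`similarity = "latent"`), or symmetric
#' uniform noise (`similarity = "random"`) for robustness checks. A
#' degenerate all-zero or all-one `Y` triggers regeneration with a warning,
#' up to `max_retries` times.
#'
#' @param m,n numbers of drugs and targets.
#' @param r_true planted latent dimensionality.
#' @param scale signal strength; inner products have standard deviation
#'   about `scale^2 / sqrt(r_true)` logits.
#' @param density target mean interaction probability.
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @param similarity `"latent"` or `"random"`.
#' @param max_retries bounded retries for degenerate draws.
#' @return list with `dataset` (a `dti_dataset`) and `truth` (list with
#'   `U`, `V`, `intercept`, `P` — the planted model).
#' @export
generate_planted_dataset <- function(m = 60, n = 60, r_true = 5, scale = 3,
                                     density = 0.1, seed = 1L,
                                     similarity = c("latent", "random"),
                                     max_retries = 10L) {
  similarity <- match.arg(similarity)
  if (m < 1 || n < 1 || r_true < 1) stop_validation("dimensions must be positive")
  if (scale <= 0) stop_validation("scale must be > 0")
  if (density <= 0 || density >= 1) stop_validation("density must be in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  for (attempt in seq_len(max_retries)) {
    set.seed(seed + (attempt - 1L) * 100003L)
    sd0 <- scale / sqrt(r_true)
    U <- matrix(stats::rnorm(m * r_true, 0, sd0), m, r_true)
    V <- matrix(stats::rnorm(n * r_true, 0, sd0), n, r_true)
    X <- tcrossprod(U, V)
    b <- stats::uniroot(function(b) mean(stats::plogis(X + b)) - density,
                        interval = c(-60, 60), tol = 1e-10)$root
    P <- stats::plogis(X + b)
    Y <- matrix(stats::rbinom(m * n, 1, P), m, n)
    if (sum(Y) > 0 && sum(Y) < m * n) {
      drug_ids <- sprintf("D%03d", seq_len(m))
      target_ids <- sprintf("T%03d", seq_len(n))
      dimnames(Y) <- list(drug_ids, target_ids)
      if (similarity == "latent") {
        Sd <- latent_similarity(U)
        St <- latent_similarity(V)
      } else {
        rand_sim <- function(k) {
          S <- matrix(stats::runif(k * k), k, k)
          S <- (S + t(S)) / 2
          diag(S) <- 1
          S
        }
        Sd <- rand_sim(m)
        St <- rand_sim(n)
      }
      ds <- dti_dataset(Y, Sd, St, drug_ids, target_ids)
      return(list(dataset = ds,
                  truth = list(U = U, V = V, intercept = b, P = P)))
    }
    warning(sprintf("degenerate interaction draw (attempt %d); regenerating", attempt))
  }
  stop_validation("could not draw a non-degenerate Y in %d attempts", max_retries)
}

# Shapes and interaction counts of the four public benchmark collections.
benchmark_profiles <- function() {
  tibble::tribble(
    ~profile, ~m, ~n, ~n_interactions,
    "nuclear_receptor", 54L, 26L, 90L,
    "gpcr", 223L, 95L, 635L,
    "ion_channel", 210L, 204L, 1476L,
    "enzyme", 445L, 664L, 2926L
  )
}

#' Generate a dataset shaped like one of the public benchmarks
#'
#' A planted dataset whose drug/target counts match the named benchmark
#' collection and whose interaction density is calibrated to its sparsity
#' (nuclear receptor 54 x 26 with about 90 interactions, GPCR 223 x 95,
#' ion channel 210 x 204, enzyme 445 x 664). Intended for shape- and
#' scale-faithful integration tests without downloading anything.
#'
#' @param profile one of `"nuclear_receptor"`, `"gpcr"`, `"ion_channel"`,
#'   `"enzyme"`.
#' @param seed integer seed.
#' @param r_true,scale planted-model parameters, see
#'   [generate_planted_dataset()].
#' @return a `dti_dataset`.
#' @export
generate_benchmark_like <- function(profile = c("nuclear_receptor", "gpcr",
                                                "ion_channel", "enzyme"),
                                    seed = 1L, r_true = 5, scale = 3) {
  profile <- match.arg(profile)
  prof <- benchmark_profiles()
  row <- prof[prof$profile == profile, ]
  generate_planted_dataset(
    m = row$m, n = row$n, r_true = r_true, scale = scale,
    density = row$n_interactions / (row$m * row$n), seed = seed)$dataset
}

#' Write a dataset as a fixture directory of three labeled TSV files
#'
#' Emits `Y.tsv`, `Sd.tsv` and `St.tsv` in the benchmark dialect (drugs on
#' rows of `Y`); [load_dataset()] round-trips them exactly.
#'
#' @param ds a `dti_dataset`.
#' @param dir directory to create/fill.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop_io("cannot create fixture directory '%s'", dir)
  }
  paths <- c(Y = file.path(dir, "Y.tsv"),
             Sd = file.path(dir, "Sd.tsv"),
             St = file.path(dir, "St.tsv"))
  write_labeled_matrix(ds$Y, paths["Y"])
  write_labeled_matrix(ds$Sd, paths["Sd"])
  write_labeled_matrix(ds$St, paths["St"])
  invisible(paths)
}
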