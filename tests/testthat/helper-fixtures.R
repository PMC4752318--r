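# In-code fixtures and independent oracles shared across the suite.

# Tiny labeled dataset with hand-set entries.
tiny_dataset <- function() {
  Y <- matrix(c(1, 0, 0,
                0, 1, 1,
                0, 0, 0,
                1, 0, 0), 4, 3, byrow = TRUE,
              dimnames = list(paste0("D", 1:4), paste0("T", 1:3)))
  Sd <- matrix(c(1, .9, .2, .4,
                 .9, 1, .3, .1,
                 .2, .3, 1, .6,
                 .4, .1, .6, 1), 4, 4, byrow = TRUE,
               dimnames = list(rownames(Y), rownames(Y)))
  St <- matrix(c(1, .5, .2,
                 .5, 1, .7,
                 .2, .7, 1), 3, 3, byrow = TRUE,
               dimnames = list(colnames(Y), colnames(Y)))
  dti_dataset(Y, Sd, St)
}

# Brute-force pairwise AUC: P(score+ > score-) + 0.5 P(tie).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force threshold-walk average precision (step interpolation).
aupr_oracle <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  np <- sum(labels == 1)
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / np
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Scalar-loop objective for the plain weighted logistic model (no Laplacian):
# per-pair weighted log-loss plus spherical Gaussian priors.
objective_scalar_oracle <- function(U, V, Y, c, lambda_d, lambda_t) {
  total <- 0
  for (i in seq_len(nrow(U))) for (j in seq_len(nrow(V))) {
    x <- sum(U[i, ] * V[j, ])
    y <- Y[i, j]
    total <- total + (1 + c * y - y) * log(1 + exp(x)) - c * y * x
  }
  total + 0.5 * lambda_d * sum(U^2) + 0.5 * lambda_t * sum(V^2)
}

# Central finite differences of the objective in every coordinate of U and V.
fd_gradients <- function(U, V, Y, hyper, Ld, Lt, eps = 1e-6) {
  g_of <- function(U, V) nrlmf_objective(U, V, Y, hyper, Ld, Lt)
  Gd <- U; Gt <- V
  for (idx in seq_along(U)) {
    Up <- U; Um <- U
    Up[idx] <- Up[idx] + eps
    Um[idx] <- Um[idx] - eps
    Gd[idx] <- (g_of(Up, V) - g_of(Um, V)) / (2 * eps)
  }
  for (idx in seq_along(V)) {
    Vp <- V; Vm <- V
    Vp[idx] <- Vp[idx] + eps
    Vm[idx] <- Vm[idx] - eps
    Gt[idx] <- (g_of(U, Vp) - g_of(U, Vm)) / (2 * eps)
  }
  list(Gd = Gd, Gt = Gt)
}

# Printed summary table of the four public benchmark collections: counts and
# the derived rows as published (averages, sparsity %, one-interaction %).
published_benchmark_table <- function() {
  tibble::tribble(
    ~profile, ~m, ~n, ~ints, ~avg_d_per_t, ~avg_t_per_d, ~sparsity, ~pct_d1, ~pct_t1,
    "nuclear_receptor", 54, 26, 90, 3.46, 1.67, 93.59, 72.22, 30.77,
    "gpcr", 223, 95, 635, 6.68, 2.85, 97.00, 47.53, 35.79,
    "ion_channel", 210, 204, 1476, 7.24, 7.03, 96.55, 38.57, 11.27,
    "enzyme", 445, 664, 2926, 4.41, 6.58, 99.01, 39.78, 43.37
  )
}
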