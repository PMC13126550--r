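# Independent oracle implementations used across the suite. Each one is a
# deliberately plain re-derivation of the rule it checks, kept free of any
# package internals.

# status rule table, coded directly from the classification criteria
oracle_classify <- function(z, iadl, iqcode, proxy) {
  if (proxy) {
    if (is.na(iqcode)) return(NA_character_)
    if (iqcode < 3.22) return("normal")
    if (iqcode < 3.48) return("impairment")
    return("dementia")
  }
  if (is.na(z)) return(NA_character_)
  cognitive <- z <= -1.5
  functional <- !is.na(iadl) && iadl >= 4
  if (cognitive && functional) return("dementia")
  if (cognitive) return("impairment")
  if (functional && !is.na(iqcode) && iqcode >= 3.22) return("impairment")
  "normal"
}

# brute-force KNN mean imputation under the partial-distance convention
oracle_knn <- function(x, k) {
  n <- nrow(x); p <- ncol(x)
  dist2 <- function(i, j) {
    both <- !is.na(x[i, ]) & !is.na(x[j, ])
    if (!any(both)) return(Inf)
    sum((x[i, both] - x[j, both])^2) * p / sum(both)
  }
  out <- x
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      if (!is.na(x[i, j])) next
      cand <- setdiff(which(!is.na(x[, j])), i)
      d <- vapply(cand, function(jj) dist2(i, jj), numeric(1))
      cand <- cand[is.finite(d)]
      d <- d[is.finite(d)]
      ord <- cand[order(d, cand)]
      nn <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(x[nn, j])
    }
  }
  out
}

# pairwise-concordance AUC (Mann-Whitney, ties counted one half)
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# out-of-bag error by explicit vote counting over a ranger fit
oracle_oob <- function(fit, x, y) {
  d <- data.frame(x, check.names = FALSE)
  per_tree <- predict(fit, data = d, predict.all = TRUE,
                      num.threads = 1)$predictions
  y <- as.integer(droplevels(as.factor(y)))
  wrong <- 0; counted <- 0
  for (i in seq_len(nrow(d))) {
    oob_trees <- which(vapply(fit$inbag.counts,
                              function(cnt) cnt[i] == 0, logical(1)))
    if (!length(oob_trees)) next
    votes <- tabulate(per_tree[i, oob_trees], nbins = max(y))
    pred <- which.max(votes)  # ties to the first class
    counted <- counted + 1
    if (pred != y[i]) wrong <- wrong + 1
  }
  wrong / counted
}

gini_impurity <- function(counts) 1 - sum((counts / sum(counts))^2)

# simulated scored-like table with a known linear norm structure
make_linear_norm_data <- function(n, sigma, beta_age = -0.03, beta_sex = 0.05,
                                  beta_edu = 0.04, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    age <- sample(seq(52, 92, 5), n, replace = TRUE)
    sex <- rbinom(n, 1, 0.5)
    edu <- sample(c(0, 4, 8, 10, 11, 15), n, replace = TRUE)
    gz <- 0.2 + beta_age * age + beta_sex * sex + beta_edu * edu +
      rnorm(n, 0, sigma)
    data.frame(global_z = gz, age_years = age, sex01 = sex,
               education_years = edu)
  })
}
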