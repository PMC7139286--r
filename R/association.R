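# SNP filtering, kinship-aware mixed-model association, q-value control,
# and additive/dominance effect decomposition.

#' Filter a genotype matrix for association analysis
#'
#' Drops SNPs with minor allele frequency below `maf_min`, missing-data
#' fraction above `missing_max`, or fewer than `min_class` individuals in
#' either minor-allele-carrying genotype class (heterozygote or
#' minor-allele homozygote).
#'
#' @param genotypes Individuals x SNPs matrix coded 0/1/2 with NA missing.
#' @param maf_min MAF threshold; SNPs strictly below are excluded
#'   (default 0.05).
#' @param missing_max Maximum missing fraction (default 0.25).
#' @param min_class Minimum individuals per alternative genotype class
#'   (default 3).
#' @return The retained columns of `genotypes`, with a `stats` attribute
#'   (data.table: snp, maf, missing, kept).
#' @export
filter_snps <- function(genotypes, maf_min = 0.05, missing_max = 0.25,
                        min_class = 3L) {
  G <- as.matrix(genotypes)
  maf <- apply(G, 2, function(g) {
    p <- mean(g, na.rm = TRUE) / 2
    if (is.nan(p)) 0 else min(p, 1 - p)
  })
  miss <- colMeans(is.na(G))
  class_ok <- apply(G, 2, function(g) {
    p <- mean(g, na.rm = TRUE) / 2
    minor_hom <- if (is.nan(p) || p <= 0.5) 2L else 0L
    sum(g == 1L, na.rm = TRUE) >= min_class &&
      sum(g == minor_hom, na.rm = TRUE) >= min_class
  })
  keep <- maf >= maf_min & miss <= missing_max & class_ok
  stats <- data.table::data.table(snp = colnames(G), maf = maf,
                                  missing = miss, kept = keep)
  out <- G[, keep, drop = FALSE]
  attr(out, "stats") <- stats
  out
}

#' Genomic relationship matrix (VanRaden)
#'
#' Centred-and-scaled genotype cross-product,
#' `K = W W' / (2 sum p_j (1 - p_j))` with `W = G - 2p`; missing genotypes
#' are imputed to the per-SNP mean. Symmetric and positive semi-definite
#' by construction.
#'
#' @param genotypes Individuals x SNPs 0/1/2 matrix (NA allowed).
#' @return Individuals x individuals relationship matrix.
#' @export
grm <- function(genotypes) {
  G <- as.matrix(genotypes)
  p <- colMeans(G, na.rm = TRUE) / 2
  W <- sweep(G, 2, 2 * p)
  W[is.na(W)] <- 0
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic; GRM undefined",
                       call. = FALSE)
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

# Profile-REML criterion for delta = sigma_e^2 / sigma_g^2 on the
# eigenbasis of K: y~ = U'y, X~ = U'X, weights w = lambda + delta.
.reml_neg2ll <- function(log_delta, yt, Xt, lambda) {
  delta <- exp(log_delta)
  w <- lambda + delta
  sw <- sqrt(w)
  Xw <- Xt / sw
  yw <- yt / sw
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  n <- length(yt); p <- fit$rank
  XtX <- crossprod(Xw[, seq_len(ncol(Xw)), drop = FALSE])
  ld <- determinant(XtX, logarithm = TRUE)$modulus
  (n - p) * log(rss / (n - p)) + sum(log(w)) + as.numeric(ld)
}

# weighted regression at a fixed delta; returns rss and rank
.gls_rss <- function(yt, Xt, lambda, delta) {
  w <- sqrt(lambda + delta)
  fit <- stats::lm.fit(Xt / w, yt / w)
  list(rss = sum(fit$residuals^2), rank = fit$rank,
       coef = fit$coefficients)
}

#' Mixed-linear-model SNP association
#'
#' Fits `y = mu + Q beta + x_add * a + x_het * d + u + e` with
#' `cov(u) = sigma_g^2 K`, estimating the variance ratio by restricted
#' maximum likelihood on the spectral decomposition of `K` (one-dimensional
#' profile optimisation). SNP significance is an F-test of the joint SNP
#' terms (additive coding plus heterozygote indicator; the dominance term
#' is dropped when fewer than 2 heterozygotes are present); `r_squared` is
#' the share of the covariate-adjusted sum of squares explained by the SNP
#' terms on the transformed (whitened) scale. With `K = NULL` (or the
#' identity) the test reduces exactly to the ordinary-least-squares F-test.
#'
#' @param y Numeric phenotype vector.
#' @param snp 0/1/2 genotype vector (NA dropped casewise).
#' @param Q Optional matrix of structure covariates.
#' @param K Optional kinship matrix (e.g. from [grm()]).
#' @param eig Optional precomputed `eigen(K, symmetric = TRUE)` (used by
#'   [assoc_scan()] to avoid repeated decompositions); must match `K`.
#' @return List: p_value, r_squared, f_stat, df, delta (REML variance
#'   ratio), n.
#' @export
mlm_assoc <- function(y, snp, Q = NULL, K = NULL, eig = NULL) {
  ok <- !is.na(y) & !is.na(snp)
  y <- y[ok]; snp <- snp[ok]
  n <- length(y)
  if (length(unique(snp)) < 2L)
    stop("SNP needs >= 2 genotype classes", call. = FALSE)
  X0 <- cbind(intercept = rep(1, n))
  if (!is.null(Q)) {
    Qm <- as.matrix(Q)[ok, , drop = FALSE]
    keep <- qr(cbind(X0, Qm))$rank == 1L + seq_len(ncol(Qm))
    if (qr(cbind(X0, Qm))$rank < 1L + ncol(Qm)) {
      warning("collinear structure covariate(s) dropped")
      Qm <- Qm[, seq_len(qr(cbind(X0, Qm))$rank - 1L), drop = FALSE]
    }
    X0 <- cbind(X0, Qm)
  }
  Xsnp <- cbind(add = snp)
  if (sum(snp == 1L) >= 2L && length(unique(snp)) == 3L)
    Xsnp <- cbind(Xsnp, het = as.numeric(snp == 1L))
  X1 <- cbind(X0, Xsnp)

  if (is.null(K)) {
    lambda <- rep(1, n); U <- NULL
    yt <- y; X0t <- X0; X1t <- X1
  } else {
    if (is.null(eig)) eig <- eigen(K[ok, ok, drop = FALSE],
                                   symmetric = TRUE)
    lambda <- pmax(eig$values, 0)
    U <- eig$vectors
    yt <- crossprod(U, y)[, 1]
    X0t <- crossprod(U, X0); X1t <- crossprod(U, X1)
  }

  opt <- optimize(.reml_neg2ll, interval = c(log(1e-5), log(1e5)),
                  yt = yt, Xt = X1t, lambda = lambda)
  delta <- exp(opt$minimum)
  full <- .gls_rss(yt, X1t, lambda, delta)
  red <- .gls_rss(yt, X0t, lambda, delta)
  q <- full$rank - red$rank
  df2 <- n - full$rank
  f <- ((red$rss - full$rss) / q) / (full$rss / df2)
  p <- pf(f, q, df2, lower.tail = FALSE)
  list(p_value = p,
       r_squared = max(0, min(1, (red$rss - full$rss) / red$rss)),
       f_stat = f, df = c(q, df2), delta = delta, n = n)
}

#' Additive/dominance decomposition of a SNP's genotypic effect
#'
#' With genotype-class means `m0`, `m1`, `m2` (major-allele homozygote,
#' heterozygote, minor-allele homozygote), the additive effect is half the
#' homozygote difference, `a = (m2 - m0) / 2`, and the dominance effect is
#' the heterozygote deviation from the homozygote midpoint,
#' `d = m1 - (m0 + m2) / 2`. A locus is a prominent dominant-effect locus
#' when `|d| / |a| > 2` strictly; with `a = 0` the ratio is an infinite
#' sentinel and the locus is prominent iff `|d| > 0`.
#'
#' @param y_adjusted Phenotype (optionally covariate-adjusted).
#' @param genotype 0/1/2 vector (NA dropped casewise).
#' @param min_class Minimum individuals per class (default 3); below it
#'   the decomposition is returned as NA.
#' @return List: a, d, d_over_a, prominent_dominant, class_means,
#'   class_n.
#' @export
effect_decomposition <- function(y_adjusted, genotype, min_class = 3L) {
  ok <- !is.na(y_adjusted) & !is.na(genotype)
  y <- y_adjusted[ok]; g <- genotype[ok]
  nn <- vapply(0:2, function(k) sum(g == k), integer(1))
  if (any(nn < min_class))
    return(list(a = NA_real_, d = NA_real_, d_over_a = NA_real_,
                prominent_dominant = NA,
                class_means = rep(NA_real_, 3), class_n = nn))
  m <- vapply(0:2, function(k) mean(y[g == k]), numeric(1))
  a <- (m[3] - m[1]) / 2
  d <- m[2] - (m[1] + m[3]) / 2
  ratio <- if (a == 0) {
    if (abs(d) > 0) Inf else NA_real_
  } else abs(d) / abs(a)
  list(a = a, d = d, d_over_a = ratio,
       prominent_dominant = isTRUE(ratio > 2),
       class_means = m, class_n = nn)
}

#' Q-values and joint significance flags
#'
#' Storey-style positive-FDR q-values in the conservative lambda = 0
#' variant, which coincides with Benjamini-Hochberg step-up adjustment.
#' Association significance requires both `p < p_threshold` and
#' `q < q_threshold`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q_threshold FDR threshold (default 0.10).
#' @param p_threshold Raw-p threshold (default 0.001).
#' @return data.table: p_value, q_value, significant.
#' @export
qvalues <- function(p_values, q_threshold = 0.10, p_threshold = 0.001) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  q <- p.adjust(p_values, method = "BH")
  data.table::data.table(p_value = p_values, q_value = q,
                         significant = p_values < p_threshold &
                           q < q_threshold)
}

#' Genome scan: mixed-model association + effect decomposition per SNP
#'
#' Runs [mlm_assoc()] and [effect_decomposition()] for every SNP of a
#' genotype matrix against one trait, then applies [qvalues()]. The
#' kinship eigendecomposition is computed once. SNPs with fewer than two
#' genotype classes are skipped (NA row).
#'
#' @param y Phenotype vector.
#' @param genotypes Individuals x SNPs 0/1/2 matrix.
#' @param Q,K Optional structure covariates and kinship matrix.
#' @param trait Trait name recorded in the output (default "trait").
#' @inheritParams qvalues
#' @return data.table: snp_id, trait, p_value, q_value, significant,
#'   r_squared, a, d, d_over_a, prominent_dominant.
#' @export
assoc_scan <- function(y, genotypes, Q = NULL, K = NULL, trait = "trait",
                       q_threshold = 0.10, p_threshold = 0.001) {
  G <- as.matrix(genotypes)
  eig <- if (!is.null(K)) eigen(K, symmetric = TRUE) else NULL
  rows <- lapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    complete <- !is.na(g) & !is.na(y)
    res <- if (length(unique(g[complete])) < 2L) {
      list(p_value = NA_real_, r_squared = NA_real_)
    } else if (all(complete)) {
      mlm_assoc(y, g, Q, K, eig = eig)
    } else {
      mlm_assoc(y, g, Q, K)  # casewise deletion breaks the shared eigen
    }
    dec <- effect_decomposition(y, g)
    data.table::data.table(
      snp_id = colnames(G)[j] %||% paste0("snp", j),
      p_value = res$p_value, r_squared = res$r_squared,
      a = dec$a, d = dec$d, d_over_a = dec$d_over_a,
      prominent_dominant = dec$prominent_dominant)
  })
  out <- data.table::rbindlist(rows)
  qq <- qvalues(ifelse(is.na(out$p_value), 1, out$p_value),
                q_threshold, p_threshold)
  out[, `:=`(trait = trait, q_value = qq$q_value,
             significant = qq$significant & !is.na(p_value))]
  data.table::setcolorder(out, c("snp_id", "trait", "p_value", "q_value",
                                 "significant", "r_squared", "a", "d",
                                 "d_over_a", "prominent_dominant"))
  out[]
}
utils::globalVariables(c("p_value", "q_value", "snp_id"))
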