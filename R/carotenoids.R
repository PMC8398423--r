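#' Carotenoid profiles and provitamin-A arithmetic
#'
#' A carotenoid profile holds the five grain carotenoid concentrations, in
#' micrograms per gram: lutein, zeaxanthin, beta-cryptoxanthin,
#' alpha-carotene, and beta-carotene (the all-trans plus cis-isomer
#' aggregate).  Provitamin A is the beta-carotene aggregate plus 50% each of
#' alpha-carotene and beta-cryptoxanthin, reflecting their half retinol
#' activity.
#'
#' @param lutein,zeaxanthin,beta_cryptoxanthin,alpha_carotene,beta_carotene
#'   concentrations in ug/g, all `>= 0`; vectors are recycled to a common
#'   length, so a set of profiles can be built at once.
#' @return A data.frame of class `carotenoid_profile` with the five
#'   concentration columns.
#' @export
carotenoid_profile <- function(lutein, zeaxanthin, beta_cryptoxanthin,
                               alpha_carotene, beta_carotene) {
  d <- data.frame(lutein = lutein, zeaxanthin = zeaxanthin,
                  beta_cryptoxanthin = beta_cryptoxanthin,
                  alpha_carotene = alpha_carotene,
                  beta_carotene = beta_carotene)
  if (any(!is.finite(as.matrix(d)))) stop("concentrations must be finite")
  if (any(as.matrix(d) < 0)) stop("concentrations must be >= 0")
  class(d) <- c("carotenoid_profile", class(d))
  d
}

.carotenoid_names <- c("lutein", "zeaxanthin", "beta_cryptoxanthin",
                       "alpha_carotene", "beta_carotene")

.as_profile <- function(profile) {
  if (is.matrix(profile) && !is.null(colnames(profile))) {
    profile <- as.data.frame(profile)
  }
  if (is.data.frame(profile)) {
    miss <- setdiff(.carotenoid_names, names(profile))
    if (length(miss)) stop("profile lacks column(s): ",
                           paste(miss, collapse = ", "))
    m <- as.matrix(profile[, .carotenoid_names, drop = FALSE])
  } else if (is.numeric(profile) && !is.null(names(profile))) {
    miss <- setdiff(.carotenoid_names, names(profile))
    if (length(miss)) stop("profile lacks entry(s): ",
                           paste(miss, collapse = ", "))
    m <- matrix(profile[.carotenoid_names], 1,
                dimnames = list(NULL, .carotenoid_names))
  } else {
    stop("profile must be a carotenoid_profile / data.frame or named vector")
  }
  if (any(!is.finite(m))) stop("concentrations must be finite")
  if (any(m < 0)) stop("concentrations must be >= 0")
  m
}

#' Provitamin A content
#'
#' \deqn{PVA = \beta\text{-carotene} + 0.5\,(\alpha\text{-carotene} +
#'   \beta\text{-cryptoxanthin})}
#' with beta-carotene as the all-trans + cis aggregate, in ug/g.
#'
#' @param profile a [carotenoid_profile()], a data.frame with the five
#'   carotenoid columns, or a named vector.
#' @return Provitamin A in ug/g (one value per profile row).
#' @export
provitamin_a <- function(profile) {
  m <- .as_profile(profile)
  unname(m[, "beta_carotene"] +
           0.5 * (m[, "alpha_carotene"] + m[, "beta_cryptoxanthin"]))
}

#' Total carotenoid content
#'
#' Sum of the five measured carotenoid concentrations, in ug/g.
#'
#' @inheritParams provitamin_a
#' @return Total carotenoids in ug/g (one value per profile row).
#' @export
total_carotenoids <- function(profile) {
  m <- .as_profile(profile)
  unname(rowSums(m))
}

#' Mean percentage share of each carotenoid
#'
#' Each profile's concentrations are expressed as percentages of its own
#' total (so shares sum to 100 within a profile); the mean share across
#' profiles is reported.  Profiles with a zero total are excluded with a
#' warning.
#'
#' @inheritParams provitamin_a
#' @return Named vector of mean percentage shares (sums to 100).
#' @export
proportions <- function(profile) {
  m <- .as_profile(profile)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-total profile(s) excluded")
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (!nrow(m)) stop("no profile with a positive total")
  shares <- sweep(m, 1L, tot, `/`) * 100
  colMeans(shares)
}

#' Percent change of group means against a benchmark profile
#'
#' \deqn{100\,(\bar x_{group} - x_{bench}) / x_{bench}} per carotenoid —
#' e.g. biofortified hybrids against an orange commercial benchmark.
#'
#' @param group_profiles profiles of the group (rows averaged).
#' @param benchmark_profile single benchmark profile, all concentrations
#'   `> 0`.
#' @return Named vector of percent changes.
#' @export
benchmark_change <- function(group_profiles, benchmark_profile) {
  g <- .as_profile(group_profiles)
  b <- .as_profile(benchmark_profile)
  if (nrow(b) != 1L) stop("benchmark must be a single profile")
  if (any(b <= 0)) stop("benchmark concentrations must be > 0")
  100 * (colMeans(g) - b[1, ]) / b[1, ]
}

#' Append derived provitamin A and total columns to a profile table
#'
#' @inheritParams provitamin_a
#' @return data.frame with `provitamin_a` and `total_carotenoids` appended.
#' @export
carotenoid_metrics <- function(profile) {
  m <- .as_profile(profile)
  out <- as.data.frame(m)
  if (is.data.frame(profile) && !is.null(rownames(profile))) {
    rownames(out) <- rownames(profile)
  }
  out$provitamin_a <- provitamin_a(out)
  out$total_carotenoids <- total_carotenoids(out[, .carotenoid_names])
  out
}
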