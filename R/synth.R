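#' Lognormal parameters from arithmetic moments
#'
#' Moment matching for fluorescence simulation: returns the log-location
#' and log-scale of the lognormal distribution whose arithmetic mean is
#' `mean` and whose coefficient of variation (SD/mean) is `cv`. With
#' `cv = 0` the distribution degenerates to a point mass at `mean`
#' (log-scale 0).
#'
#' @param mean Arithmetic mean, a.u., must be > 0.
#' @param cv Coefficient of variation as a fraction (not percent), >= 0.
#' @return Named numeric vector `c(log_location, log_scale)` (natural
#'   log).
#' @examples
#' p <- lognormal_from_moments(100, 0.5)
#' x <- rlnorm(1e5, p["log_location"], p["log_scale"])
#' c(mean(x), sd(x) / mean(x))  # ~100, ~0.5
#' @export
lognormal_from_moments <- function(mean, cv) {
  if (!is.finite(mean) || mean <= 0)
    stop("domain error: mean must be > 0", call. = FALSE)
  if (!is.finite(cv) || cv < 0)
    stop("domain error: cv must be >= 0", call. = FALSE)
  s2 <- log1p(cv^2)
  c(log_location = log(mean) - s2 / 2, log_scale = sqrt(s2))
}

# n lognormal draws with arithmetic mean m and CV (fraction); cv = 0 is a
# point mass
rlnorm_moments <- function(n, m, cv) {
  if (n == 0L) return(numeric(0))
  if (cv == 0) return(rep.int(m, n))
  p <- lognormal_from_moments(m, cv)
  stats::rlnorm(n, p[[1]], p[[2]])
}

## ---------------------------------------------------------------------------
## Mixture-moment inversion: published tables print percent positive plus
## MFI/CV either over all subset events or over positive cells only. The
## generator needs the positive component's (mean, CV). For all-event
## tables, with positive fraction q, background (mn, cvn):
##   M_all  = q*mp + (1-q)*mn
##   E[X^2] = q*(vp + mp^2) + (1-q)*(vn + mn^2)
## ---------------------------------------------------------------------------

invert_mfi_all <- function(mfi_all, q, mn, fallback = 30) {
  if (q < 0.02) return(fallback)
  mp <- (mfi_all - (1 - q) * mn) / q
  if (!is.finite(mp) || mp <= mn * 1.2) return(fallback)
  min(mp, 10000)
}

# Observed-to-latent positive-fraction calibration. Published percent
# positive is a cutoff-based observed quantity: with an upper-quantile
# isotype cutoff c, a latent positive fraction f is observed as
#   q_obs = f * P(pos >= c) + (1 - f) * (1 - iso_q).
# Solving for f (given the fitted positive component and the nominal
# isotype quantile) makes the generated gated percent positive reproduce
# the printed one even for dim positives that straddle the cutoff.
calibrate_frac <- function(q, mp, cvp, mn, cvn, iso_q = 0.995) {
  if (q <= 0) return(0)
  pn <- lognormal_from_moments(mn, cvn)
  c_nom <- stats::qlnorm(iso_q, pn[[1]], pn[[2]])
  fp <- 1 - iso_q
  pp <- if (cvp == 0) {
    as.numeric(mp >= c_nom)
  } else {
    pl <- lognormal_from_moments(mp, cvp)
    1 - stats::plnorm(c_nom, pl[[1]], pl[[2]])
  }
  if (pp <= fp + 0.005) return(q)  # positives indistinguishable from background
  min(1, max(0, (q - fp) / (pp - fp)))
}

invert_cv_all <- function(mfi_all, cv_all, q, mp, mn, cvn, fallback = 0.6) {
  if (q < 0.02 || mp <= mn * 1.2) return(fallback)
  vn <- (cvn * mn)^2
  e2 <- (cv_all / 100 * mfi_all)^2 + mfi_all^2
  vp <- (e2 - (1 - q) * (vn + mn^2)) / q - mp^2
  if (!is.finite(vp) || vp <= (0.05 * mp)^2) return(fallback)
  min(sqrt(vp) / mp, 3)
}

# latent lognormal mean whose mean below a clip point b equals m_obs
# (the printed CD56+int MFI is measured below the int/high boundary, so
# the generating distribution must sit somewhat higher)
clip_invert_lnorm <- function(m_obs, cv, b) {
  s <- sqrt(log1p(cv^2))
  f <- function(m) {
    mu <- log(m) - s^2 / 2
    zc <- (log(b) - mu) / s
    m * stats::pnorm(zc - s) / stats::pnorm(zc) - m_obs
  }
  if (!is.finite(f(m_obs)) || f(m_obs) >= 0) return(m_obs)
  hi <- m_obs * 3
  if (f(hi) < 0) return(hi)
  stats::uniroot(f, c(m_obs, hi), tol = 1e-8)$root
}

## ---------------------------------------------------------------------------
## Gate-exchange model. Hard gates on overlapping distributions exchange
## events between neighbouring subsets (int <-> high across the CD56
## boundary, PE false-positives from the low subset, CD56 background
## false-positives from non-NK cells). The printed per-subset percent
## positive values are post-gate quantities; the generator therefore
## inverts the expected 3x3 mixing matrix so that gated statistics
## reproduce the printed ones. All exchange rates are computed from the
## profile sheet's own cohort-level parameters.
## ---------------------------------------------------------------------------

build_exchange_model <- function(profile) {
  tryCatch({
    bg <- profile$background
    mn <- bg$mfi; cvn <- bg$cv
    pn <- lognormal_from_moments(mn, cvn)
    c_nom <- stats::qlnorm(0.995, pn[[1]], pn[[2]])
    fp <- 0.005
    tw <- profile$threeway$CD56
    m_l <- tw$NK_low$mfi$mean;  cv_l <- tw$NK_low$cv / 100
    m_i <- tw$NK_int$mfi$mean;  cv_i <- tw$NK_int$cv / 100
    m_h <- tw$NK_high$mfi$mean; cv_h <- tw$NK_high$cv / 100
    sh <- vapply(c("NK_low", "NK_int", "NK_high"),
                 function(s) profile$shares[[s]]$mean, numeric(1))
    sh <- 100 * sh / sum(sh)
    p1h <- profile$protocol1$CXCR3$high
    mp_pool <- invert_mfi_all(p1h$mfi$mean, p1h$pct$mean / 100, mn)
    cv_pool <- invert_cv_all(p1h$mfi$mean, p1h$cv, p1h$pct$mean / 100,
                             mp_pool, mn, cvn)
    pl <- lognormal_from_moments(mp_pool, cv_pool)
    pp <- 1 - stats::plnorm(c_nom, pl[[1]], pl[[2]])
    # CD56 int/high boundary and latent int location, by fixed point
    m_lat <- m_i
    b <- NA_real_
    for (k in 1:4) {
      li <- lognormal_from_moments(m_lat, cv_i)
      lh <- lognormal_from_moments(m_h, cv_h)
      xb <- equal_density_crossing(c(li[[1]], lh[[1]]),
                                   c(li[[2]], lh[[2]]),
                                   c(sh[2], sh[3]) / (sh[2] + sh[3]))
      b <- exp(xb)
      m_lat <- clip_invert_lnorm(m_i, cv_i, b)
    }
    li <- lognormal_from_moments(m_lat, cv_i)
    lh <- lognormal_from_moments(m_h, cv_h)
    ll <- lognormal_from_moments(m_l, cv_l)
    e_ih <- 1 - stats::plnorm(b, li[[1]], li[[2]])
    e_hi <- stats::plnorm(b, lh[[1]], lh[[2]])
    e_lh <- 1 - stats::plnorm(b, ll[[1]], ll[[2]])
    freq <- unlist(profile$population_frequencies)
    fb <- 100 * (freq[["B"]] + freq[["other"]]) * fp / freq[["NK"]]
    w_low  <- c(sh[1] * (1 - fp), sh[2] * (1 - pp), sh[3] * (1 - pp))
    w_int  <- c(sh[1] * fp * (1 - e_lh), sh[2] * pp * (1 - e_ih),
                sh[3] * pp * e_hi)
    w_high <- c(sh[1] * fp * e_lh, sh[2] * pp * e_ih,
                sh[3] * pp * (1 - e_hi))
    tots <- c(sum(w_low) + fb, sum(w_int), sum(w_high))
    W <- rbind(w_low / tots[1], w_int / tots[2], w_high / tots[3])
    bg_term <- c(fb / tots[1] * (100 * fp), 0, 0)
    # conventional-split mixing (CD56 boundary AND CD16-negativity for
    # the high gate): CD16+ high cells and boundary exchange fold into
    # the conventional low gate; false-NK events dilute it further
    cd16 <- profile$threeway$CD16
    p16neg <- c(low = 1 - cd16$NK_low$pct$mean / 100,
                int = 1 - cd16$NK_int$pct$mean / 100,
                high = 1 - cd16$NK_high$pct$mean / 100)
    w1 <- c(sh[1],
            sh[2] * (1 - e_ih * p16neg[["int"]]),
            sh[3] * (1 - (1 - e_hi) * p16neg[["high"]]))
    w2 <- c(sh[1] * e_lh * p16neg[["low"]],
            sh[2] * e_ih * p16neg[["int"]],
            sh[3] * (1 - e_hi) * p16neg[["high"]])
    p1 <- list(w1 = w1, w2 = w2, t1 = sum(w1) + fb, t2 = sum(w2),
               fb = fb)
    list(W = W, bg_term = bg_term, b_nom = b, cv_int = cv_i, p1 = p1)
  }, error = function(e) NULL)
}

# latent per-subset percent vector reproducing drawn gated percentages
exchange_invert <- function(g3, ex) {
  v <- try(solve(ex$W, g3 - ex$bg_term), silent = TRUE)
  if (inherits(v, "try-error") || any(!is.finite(v))) return(g3)
  pmin(100, pmax(0, v))
}

## ---------------------------------------------------------------------------
## Cohort configuration
## ---------------------------------------------------------------------------

#' Read or write a cohort profile sheet
#'
#' Profile sheets are YAML documents describing per-subset marker
#' expression (percent positive, MFI, CV with between-subject SD and
#' range), subset shares, scatter and acquisition settings. The packaged
#' default sheet transcribes published reference values for normal blood
#' NK-cell subsets.
#'
#' @param path File path; for `read_profile_sheet` the default is the
#'   packaged sheet.
#' @return `read_profile_sheet`: a nested list. `write_profile_sheet`:
#'   `path`, invisibly.
#' @export
read_profile_sheet <- function(path = system.file("extdata",
                                                  "nk_profile_default.yaml",
                                                  package = "nkckr")) {
  yaml::read_yaml(path)
}

#' @rdname read_profile_sheet
#' @param profile A profile sheet list.
#' @export
write_profile_sheet <- function(profile, path) {
  yaml::write_yaml(profile, path)
  invisible(path)
}

#' Build a cohort simulation configuration
#'
#' Assembles the generator configuration from a profile sheet: the
#' drawable parameter cells (subset shares and each table cell's percent
#' and MFI, with SD and truncation range), the staining tubes (one per
#' marker, two protocols, plus an isotype tube), subject-level
#' correlated parameter pairs, and acquisition sizes.
#'
#' In protocol-1 tubes the conventional CD56+low gate pools the true
#' CD56+low and CD56+int populations, so both populations share the
#' printed "low" cell for CXCR1/CXCR2/CXCR4/CCR4/CCR6. For CXCR3 and
#' CCR5 the CD56+int population is definitionally positive (it uses the
#' "high" cell) and the true-low fraction is derived by mixture
#' inversion so the pooled gate reproduces the printed value.
#'
#' @param profile Profile sheet (list) or path to one; default packaged.
#' @param n_subjects,n_events_per_tube,isotype_events Optional overrides
#'   of the sheet's acquisition settings (`isotype_events` defaults to
#'   `n_events_per_tube`).
#' @param tubes Optional character vector restricting the simulated
#'   tubes (tube ids such as `"P1_CXCR1"`, `"P2_CD16"`; the isotype tube
#'   `"ISO"` is always kept).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- nk_cohort_config(n_subjects = 3, n_events_per_tube = 2000,
#'                         tubes = "P2_CD16", seed = 7)
#' cfg
#' @export
nk_cohort_config <- function(profile = NULL, n_subjects = NULL,
                             n_events_per_tube = NULL, isotype_events = NULL,
                             tubes = NULL, seed = 1L) {
  if (is.null(profile)) profile <- read_profile_sheet()
  if (is.character(profile)) profile <- read_profile_sheet(profile)

  n_subjects <- n_subjects %||% profile$cohort$n_subjects
  n_events <- n_events_per_tube %||% profile$cohort$n_events_per_tube
  isotype_events <- isotype_events %||% n_events
  if (n_subjects < 2L)
    stop("config error: n_subjects must be >= 2", call. = FALSE)

  cell <- function(id, x) data.frame(id = id, mean = x$mean, sd = x$sd,
                                     lo = x$min, hi = x$max)
  cells <- list()
  for (s in names(profile$shares))
    cells[[length(cells) + 1L]] <- cell(paste0("share.", s),
                                        profile$shares[[s]])
  for (m in names(profile$protocol1)) {
    for (col in c("low", "high")) {
      e <- profile$protocol1[[m]][[col]]
      cells[[length(cells) + 1L]] <- cell(sprintf("p1.%s.%s.pct", m, col),
                                          e$pct)
      cells[[length(cells) + 1L]] <- cell(sprintf("p1.%s.%s.mfi", m, col),
                                          e$mfi)
    }
  }
  # observed conventional-low cells for CXCR3/CCR5: drawn on the
  # published (gated) scale -- this is the scale on which the
  # subject-level correlation is reported -- then inverted per subject
  # to the true-low latent fraction through the gate-exchange model
  # (the CD56+int component of the conventional low gate is
  # definitionally positive for these two receptors)
  for (m in c("CXCR3", "CCR5")) {
    p <- profile$protocol1[[m]]
    cells[[length(cells) + 1L]] <- data.frame(
      id = sprintf("p1.%s.lowtrue.pct", m),
      mean = p$low$pct$mean, sd = p$low$pct$sd,
      lo = p$low$pct$min, hi = p$low$pct$max)
  }
  for (m in names(profile$threeway)) {
    for (s in c("NK_low", "NK_int", "NK_high")) {
      e <- profile$threeway[[m]][[s]]
      cells[[length(cells) + 1L]] <- cell(sprintf("t3.%s.%s.pct", m, s),
                                          e$pct)
      cells[[length(cells) + 1L]] <- cell(sprintf("t3.%s.%s.mfi", m, s),
                                          e$mfi)
    }
  }
  cells <- do.call(rbind, cells)
  bad <- cells$lo > cells$hi | cells$mean < cells$lo | cells$mean > cells$hi
  if (any(bad))
    stop("config error: infeasible range (min > max or mean outside range) ",
         "for cell(s): ", paste(cells$id[bad], collapse = ", "),
         call. = FALSE)
  # location adjustment: a normal truncated to an asymmetric (min, max)
  # range has mean != its location parameter; shift the location so the
  # realized between-subject mean reproduces the published mean
  cells$location <- mapply(truncnorm_location, cells$mean, cells$sd,
                           cells$lo, cells$hi)

  all_tubes <- list()
  for (m in names(profile$protocol1))
    all_tubes[[paste0("P1_", m)]] <- list(
      tube_id = paste0("P1_", m), protocol = "conventional",
      markers = c(FL1 = "CD16", FL2 = m, FL3 = "CD56", FL4 = "CD3"))
  for (m in setdiff(names(profile$threeway), "CD56"))
    all_tubes[[paste0("P2_", m)]] <- list(
      tube_id = paste0("P2_", m), protocol = "three_way",
      markers = c(FL1 = m, FL2 = "CXCR3+CCR5", FL3 = "CD56", FL4 = "CD3"))
  all_tubes[["ISO"]] <- list(
    tube_id = "ISO", protocol = "isotype",
    markers = c(FL1 = "isotype", FL2 = "isotype", FL3 = "isotype",
                FL4 = "isotype"))
  if (!is.null(tubes)) {
    missing <- setdiff(tubes, names(all_tubes))
    if (length(missing))
      stop("config error: unknown tube id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    all_tubes <- all_tubes[union(tubes, "ISO")]
  }

  pairs <- do.call(rbind, lapply(profile$correlated_pairs, function(p)
    data.frame(a = p$a, b = p$b, r = p$r)))
  if (!is.null(pairs)) {
    if (any(abs(pairs$r) > 1))
      stop("config error: |correlation| must be <= 1", call. = FALSE)
    missing <- setdiff(c(pairs$a, pairs$b), cells$id)
    if (length(missing))
      stop("config error: correlated pair names unknown cell(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  structure(list(profile = profile, n_subjects = as.integer(n_subjects),
                 n_events_per_tube = as.integer(n_events),
                 isotype_events = as.integer(isotype_events),
                 cells = cells, tubes = all_tubes,
                 correlated_pairs = pairs,
                 exchange = build_exchange_model(profile),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$n_subjects, "subjects,",
      x$n_events_per_tube, "events/tube (isotype", x$isotype_events, ")\n")
  cat("  tubes:", paste(names(x$tubes), collapse = ", "), "\n")
  cat("  parameter cells:", nrow(x$cells),
      "| correlated pairs:", if (is.null(x$correlated_pairs)) 0
      else nrow(x$correlated_pairs), "| seed:", x$seed, "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Subject-level parameter draws
## ---------------------------------------------------------------------------

# mean of a normal(m, sd) truncated to (lo, hi)
truncnorm_mean <- function(m, sd, lo, hi) {
  a <- (lo - m) / sd
  b <- (hi - m) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z < 1e-12) return(m)
  m + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# location parameter whose truncated-normal mean equals `target`
truncnorm_location <- function(target, sd, lo, hi) {
  if (sd == 0 || hi - lo < 1e-12) return(target)
  f <- function(m) truncnorm_mean(m, sd, lo, hi) - target
  # the truncated mean is increasing in the location; bracket widely
  lo_m <- target - 4 * sd
  hi_m <- target + 4 * sd
  if (f(lo_m) > 0 || f(hi_m) < 0) return(target)
  stats::uniroot(f, c(lo_m, hi_m), tol = 1e-10)$root
}

# truncated-normal quantile via inverse CDF (used for copula margins)
qtruncnorm <- function(u, mean, sd, lo, hi) {
  if (sd == 0) return(rep.int(mean, length(u)))
  pa <- stats::pnorm(lo, mean, sd)
  pb <- stats::pnorm(hi, mean, sd)
  stats::qnorm(pa + u * (pb - pa), mean, sd)
}

# rejection-sampled truncated normal (redraw cap per draw)
rtruncnorm_reject <- function(n, mean, sd, lo, hi, max_attempts = 1000L) {
  if (sd == 0) return(rep.int(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_attempts)) {
    bad <- x < lo | x > hi
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("config error: truncated-normal rejection exceeded ", max_attempts,
       " attempts for range [", lo, ", ", hi, "]", call. = FALSE)
}

#' Draw realized subject-level parameters
#'
#' Each scalar parameter cell is drawn from a normal distribution with
#' the cell's mean and SD, truncated to the cell's (min, max) range
#' (rejection sampling, capped at 1000 redraws). Correlated pairs are
#' realized through a Gaussian copula with truncated-normal margins.
#' Subset shares are renormalized to sum to 100. Each subject's cells
#' are then resolved into a full population profile (frequencies,
#' scatter, and per-marker positive/negative lognormal components).
#'
#' @param config A [nk_cohort_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List of subject parameter sets (class `subject_params`), one
#'   per subject, each with elements `subject_id`, `cells` (named
#'   vector of realized cell values), `frequencies` (percent per
#'   population, summing to 100), `scatter` and `expression`
#'   (population -> marker -> `c(frac, mfi_pos, cv_pos, mfi_neg,
#'   cv_neg)`).
#' @export
draw_subject_params <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_subjects
  cells <- config$cells
  pairs <- config$correlated_pairs
  paired <- if (is.null(pairs)) character(0) else c(pairs$a, pairs$b)

  draws <- matrix(NA_real_, nrow = n, ncol = nrow(cells),
                  dimnames = list(NULL, cells$id))
  for (k in seq_len(nrow(cells))) {
    if (cells$id[k] %in% paired) next
    draws[, k] <- rtruncnorm_reject(n, cells$location[k], cells$sd[k],
                                    cells$lo[k], cells$hi[k])
  }
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      r <- pairs$r[k]
      z1 <- stats::rnorm(n)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
      for (nm_z in list(c(pairs$a[k], 1), c(pairs$b[k], 2))) {
        i <- match(nm_z[1], cells$id)
        u <- stats::pnorm(if (nm_z[2] == "1") z1 else z2)
        draws[, i] <- qtruncnorm(u, cells$location[i], cells$sd[i],
                                 cells$lo[i], cells$hi[i])
      }
    }
  }

  lapply(seq_len(n), function(i) {
    resolve_subject(config, sprintf("S%02d", i), draws[i, ])
  })
}

# Turn one subject's drawn cell values into a full population profile.
resolve_subject <- function(config, subject_id, v) {
  prof <- config$profile
  bg <- prof$background
  mn <- bg$mfi
  cvn <- bg$cv
  freq <- unlist(prof$population_frequencies)
  shares <- v[paste0("share.", c("NK_low", "NK_int", "NK_high"))]
  shares <- 100 * shares / sum(shares)
  frequencies <- c(T = unname(freq["T"]), B = unname(freq["B"]),
                   other = unname(freq["other"]),
                   NK_low = unname(freq["NK"] * shares[1] / 100),
                   NK_int = unname(freq["NK"] * shares[2] / 100),
                   NK_high = unname(freq["NK"] * shares[3] / 100))

  pops <- c("T", "B", "other", "NK_low", "NK_int", "NK_high")
  nk <- c("NK_low", "NK_int", "NK_high")
  spec <- function(frac, mp, cvp) c(frac = unname(frac), mfi_pos = unname(mp),
                                    cv_pos = unname(cvp), mfi_neg = mn,
                                    cv_neg = cvn)
  # published percent positive -> latent Bernoulli fraction (see
  # calibrate_frac); applied to every table-derived spec. Independently
  # drawn (pct, MFI) cells can be jointly infeasible (positives too dim
  # to ever be observed at the drawn rate under a cutoff); in that case
  # the positive-component mean is raised to the smallest value at which
  # P(pos >= cutoff) equals the drawn fraction.
  c_nom <- {
    pn <- lognormal_from_moments(mn, cvn)
    stats::qlnorm(0.995, pn[[1]], pn[[2]])
  }
  cspec <- function(frac, mp, cvp) {
    q <- unname(frac) / 100
    if (q > 0.005 && cvp > 0) {
      sg <- sqrt(log1p(cvp^2))
      pp <- 1 - stats::pnorm((log(c_nom) - (log(mp) - sg^2 / 2)) / sg)
      if (pp < q) {
        mu_min <- log(c_nom) - sg * stats::qnorm(1 - min(q, 0.999))
        mp <- max(mp, exp(mu_min + sg^2 / 2))
      }
    }
    spec(100 * calibrate_frac(q, mp, cvp, mn, cvn), mp, cvp)
  }
  neg <- spec(0, mn, cvn)

  expression <- stats::setNames(vector("list", length(pops)), pops)
  for (p in pops) expression[[p]] <- list()

  # CD3: T-cells bright positive, everyone else background
  for (p in pops)
    expression[[p]][["CD3"]] <- if (p == "T") spec(100, 800, 0.4) else neg

  # three-way-table antigens (CD56, CD16, CD57, CD62L, CD94, CD122, CD158a)
  ex <- config$exchange
  for (m in names(prof$threeway)) {
    mode_all <- identical(prof$threeway[[m]]$mfi_mode, "all")
    fracs <- stats::setNames(v[sprintf("t3.%s.%s.pct", m, nk)], nk)
    if (!is.null(ex) && m != "CD56")
      fracs[] <- exchange_invert(unname(fracs), ex)
    for (p in pops) {
      if (!p %in% nk) { expression[[p]][[m]] <- neg; next }
      frac <- fracs[[p]]
      mfi <- v[sprintf("t3.%s.%s.mfi", m, p)]
      tab <- prof$threeway[[m]][[p]]
      if (mode_all) {
        q0 <- tab$pct$mean / 100          # CVs held at cohort-level values
        mp0 <- invert_mfi_all(tab$mfi$mean, q0, mn)
        cvp <- invert_cv_all(tab$mfi$mean, tab$cv, q0, mp0, mn, cvn)
        mp <- invert_mfi_all(mfi, frac / 100, mn)
      } else {
        mp <- mfi
        cvp <- tab$cv / 100
      }
      if (!is.null(ex) && m == "CD56" && p == "NK_int")
        mp <- clip_invert_lnorm(mp, ex$cv_int, ex$b_nom)
      expression[[p]][[m]] <- cspec(frac, mp, cvp)
    }
  }

  # protocol-1 chemokine receptors
  for (m in names(prof$protocol1)) {
    tab <- prof$protocol1[[m]]
    comp <- function(col, frac_override = NULL) {
      q0 <- tab[[col]]$pct$mean / 100
      mp0 <- invert_mfi_all(tab[[col]]$mfi$mean, q0, mn)
      cvp <- invert_cv_all(tab[[col]]$mfi$mean, tab[[col]]$cv, q0, mp0, mn,
                           cvn)
      mp <- invert_mfi_all(v[sprintf("p1.%s.%s.mfi", m, col)], q0, mn)
      frac <- frac_override %||% v[sprintf("p1.%s.%s.pct", m, col)]
      cspec(frac, mp, cvp)
    }
    definitional <- m %in% c("CXCR3", "CCR5")
    # invert the conventional-gate mixing so gated values reproduce the
    # drawn (published-scale) cells; without the exchange model fall
    # back to using the printed cells as latent fractions directly
    f_low <- f_int <- f_high <- NULL
    p1x <- if (is.null(ex)) NULL else ex$p1
    if (!is.null(p1x)) {
      g_h <- v[[sprintf("p1.%s.high.pct", m)]]
      if (definitional) {
        f_int <- f_high <- g_h
        g_l <- v[[sprintf("p1.%s.lowtrue.pct", m)]]
        f_low <- min(100, max(0,
          (g_l * p1x$t1 - (p1x$w1[2] + p1x$w1[3]) * f_high -
             p1x$fb * 0.5) / p1x$w1[1]))
      } else {
        g_l <- v[[sprintf("p1.%s.low.pct", m)]]
        a11 <- p1x$w1[1] + p1x$w1[2]; a12 <- p1x$w1[3]
        a21 <- p1x$w2[1] + p1x$w2[2]; a22 <- p1x$w2[3]
        b1 <- g_l * p1x$t1 - p1x$fb * 0.5
        b2 <- g_h * p1x$t2
        det <- a11 * a22 - a12 * a21
        u <- (b1 * a22 - a12 * b2) / det
        w <- (b2 - a21 * u) / a22
        f_low <- f_int <- min(100, max(0, u))
        f_high <- min(100, max(0, w))
      }
    } else if (definitional) {
      f_low <- v[[sprintf("p1.%s.lowtrue.pct", m)]]
    }
    for (p in pops) {
      expression[[p]][[m]] <-
        if (p == "NK_high") comp("high", frac_override = f_high)
        else if (p == "NK_int") { if (definitional)
          comp("high", frac_override = f_int)
          else comp("low", frac_override = f_int) }
        else if (p == "NK_low") { if (definitional)
          comp("low", frac_override = f_low)
          else comp("low", frac_override = f_low) }
        else neg
    }
  }

  # pooled PE channel: CXCR3 and/or CCR5 positive (definitional for
  # CD56+int/+high); intensity follows the bright CXCR3 positive component
  pooled_mp <- invert_mfi_all(v["p1.CXCR3.high.mfi"],
                              prof$protocol1$CXCR3$high$pct$mean / 100, mn)
  pooled_cv <- invert_cv_all(prof$protocol1$CXCR3$high$mfi$mean,
                             prof$protocol1$CXCR3$high$cv,
                             prof$protocol1$CXCR3$high$pct$mean / 100,
                             invert_mfi_all(prof$protocol1$CXCR3$high$mfi$mean,
                                            prof$protocol1$CXCR3$high$pct$mean / 100,
                                            mn),
                             mn, cvn)
  for (p in pops)
    expression[[p]][["CXCR3+CCR5"]] <-
      if (p %in% c("NK_int", "NK_high")) cspec(100, pooled_mp, pooled_cv)
      else neg

  for (p in pops)
    expression[[p]][["isotype"]] <- neg

  scat <- prof$scatter
  scatter <- list(event_sd = unlist(scat$event_sd))
  for (p in pops) scatter[[p]] <- unlist(scat[[p]])

  structure(list(subject_id = subject_id, cells = v,
                 frequencies = frequencies, scatter = scatter,
                 expression = expression),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params>", x$subject_id, "\n  frequencies (%):",
      paste(sprintf("%s=%.2f", names(x$frequencies), x$frequencies),
            collapse = " "), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Event-level simulation
## ---------------------------------------------------------------------------

fluorochrome_of <- c(FSC = "none", SSC = "none", FL1 = "FITC", FL2 = "PE",
                     FL3 = "PC5", FL4 = "APC")

#' Simulate one staining tube for one subject
#'
#' Each event draws a latent population by frequency, normal scatter
#' values, and for each stained channel a Bernoulli positivity indicator
#' followed by a lognormal intensity from the positive or negative
#' component. The pooled PE channel is handled through its own
#' definitional marker spec (CXCR3 and/or CCR5 positive). Intensities
#' are clipped to [0, 10000]; pile-up at the top of scale is counted,
#' not discarded. Positivity indicators are independent across markers
#' within a cell.
#'
#' @param subject A `subject_params` object from [draw_subject_params()].
#' @param tube A tube spec (list with `tube_id` and named `markers`
#'   vector `FL1`..`FL4`), e.g. one element of `config$tubes`.
#' @param n_events Number of events to draw.
#' @param seed Optional integer seed for this tube.
#' @return A [sample_events] object with extra elements `latent` (factor
#'   of true population labels, for oracle testing) and `pileup` (count
#'   of clipped intensities).
#' @export
simulate_tube <- function(subject, tube, n_events, seed = NULL) {
  stopifnot(inherits(subject, "subject_params"))
  if (!is.null(seed)) set.seed(seed)
  freq <- subject$frequencies
  pops <- names(freq)
  lat <- sample(pops, n_events, replace = TRUE, prob = freq / sum(freq))
  idx <- lapply(pops, function(p) which(lat == p))
  names(idx) <- pops

  chans <- c("FSC", "SSC", names(tube$markers))
  ev <- matrix(0, nrow = n_events, ncol = length(chans),
               dimnames = list(NULL, chans))
  esd <- subject$scatter$event_sd
  for (p in pops) {
    k <- length(idx[[p]])
    if (!k) next
    sc <- subject$scatter[[p]]
    ev[idx[[p]], "FSC"] <- stats::rnorm(k, sc[["fsc"]], esd[["fsc"]])
    ev[idx[[p]], "SSC"] <- stats::rnorm(k, sc[["ssc"]], esd[["ssc"]])
  }
  for (ch in names(tube$markers)) {
    m <- tube$markers[[ch]]
    for (p in pops) {
      k <- length(idx[[p]])
      if (!k) next
      sp <- subject$expression[[p]][[m]]
      if (is.null(sp))
        stop("config error: population '", p, "' has no expression spec ",
             "for marker '", m, "'", call. = FALSE)
      pos <- stats::runif(k) < sp[["frac"]] / 100
      vals <- numeric(k)
      vals[pos] <- rlnorm_moments(sum(pos), sp[["mfi_pos"]], sp[["cv_pos"]])
      vals[!pos] <- rlnorm_moments(sum(!pos), sp[["mfi_neg"]],
                                   sp[["cv_neg"]])
      ev[idx[[p]], ch] <- vals
    }
  }
  pileup <- sum(ev > 10000)
  ev[ev > 10000] <- 10000
  ev[ev < 0] <- 0

  chan_meta <- data.frame(
    channel_id = chans,
    fluorochrome = unname(fluorochrome_of[chans]),
    marker = c("none", "none", unname(tube$markers)),
    stringsAsFactors = FALSE)
  s <- sample_events(ev, chan_meta, subject_id = subject$subject_id,
                     tube_id = tube$tube_id)
  s$latent <- factor(lat, levels = pops)
  s$pileup <- pileup
  s
}

#' Simulate a full multi-tube cytometry cohort
#'
#' Draws subject-level parameters, then simulates every configured tube
#' (including the isotype-control tube) for every subject. Fully
#' deterministic for a fixed `config$seed`: per-tube seeds are derived
#' from it, so restricting `config$tubes` does not change the events of
#' the remaining tubes.
#'
#' @param config A [nk_cohort_config()] object.
#' @return An object of class `nk_cohort`: list with `config`, `subjects`
#'   (realized parameters) and `samples`, a nested list
#'   `samples[[subject_id]][[tube_id]]` of [sample_events] (each with
#'   latent labels).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- draw_subject_params(config)
  samples <- lapply(seq_along(subjects), function(i) {
    subj <- subjects[[i]]
    out <- lapply(seq_along(config$tubes), function(j) {
      tube <- config$tubes[[j]]
      n <- if (tube$protocol == "isotype") config$isotype_events
           else config$n_events_per_tube
      simulate_tube(subj, tube, n, seed = tube_seed(config$seed, i, j))
    })
    stats::setNames(out, names(config$tubes))
  })
  names(samples) <- vapply(subjects, `[[`, "", "subject_id")
  structure(list(config = config, subjects = subjects, samples = samples),
            class = "nk_cohort")
}

tube_seed <- function(seed, i, j) {
  as.integer((seed + 1000003 * i + 10007 * j) %% 2147483647)
}

#' @export
print.nk_cohort <- function(x, ...) {
  cat("<nk_cohort>", length(x$subjects), "subjects x",
      length(x$config$tubes), "tubes,",
      x$config$n_events_per_tube, "events/tube\n")
  invisible(x)
}
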