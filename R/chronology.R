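#' @title Bayesian radiocarbon calibration and family-constrained modeling
#' @name chronology
#' @description Calibration-curve handling in the standard `.14c` column
#'   format, diet-weighted terrestrial/marine curve mixing with a free local
#'   reservoir offset (deltaR), single-date calibration on a calendar grid,
#'   and a Metropolis-within-Gibbs sampler for a family model with
#'   per-individual birth/death events, a shared depositional event, and
#'   OxCal-style agreement indices.
NULL

#' Construct a calibration-curve object
#'
#' @param calbp calendar-year grid (cal BP), strictly monotone.
#' @param mu curve mean (14C yr BP).
#' @param sigma curve sigma (14C yr), all > 0.
#' @param name optional curve name.
#' @return object of class `calcurve`.
#' @export
calcurve <- function(calbp, mu, sigma, name = "curve") {
  o <- order(calbp)
  calbp <- calbp[o]; mu <- mu[o]; sigma <- sigma[o]
  if (length(calbp) < 2) stop("format-error: curve needs >= 2 rows")
  if (any(diff(calbp) <= 0)) stop("format-error: grid not strictly monotone")
  if (any(sigma <= 0)) stop("format-error: curve sigma must be > 0")
  structure(list(calbp = calbp, mu = mu, sigma = sigma, name = name),
            class = "calcurve")
}

#' Load a calibration curve from a `.14c` file
#'
#' Expects the standard comma- or whitespace-separated three-plus-column
#' layout (cal BP, 14C age BP, sigma), `#` comments allowed.
#'
#' @param path file path.
#' @return a [calcurve()].
#' @export
load_calcurve <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  sep <- if (any(grepl(",", ln))) "," else ""
  d <- utils::read.table(text = ln, sep = sep, header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("format-error: need >= 3 columns")
  calcurve(as.numeric(d[[1]]), as.numeric(d[[2]]), as.numeric(d[[3]]),
           name = basename(path))
}

#' Write a calibration curve in `.14c` format
#' @param curve a [calcurve()].
#' @param path output path.
#' @export
write_calcurve <- function(curve, path) {
  utils::write.table(
    data.frame(curve$calbp, curve$mu, curve$sigma),
    path, sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interpolate a curve at calendar years
#' @param curve a [calcurve()].
#' @param t_bp calendar years (cal BP).
#' @return list with `mu` and `sigma` at `t_bp`.
#' @export
curve_at <- function(curve, t_bp) {
  rng <- range(curve$calbp)
  if (any(t_bp < rng[1] | t_bp > rng[2]))
    stop("out-of-range: year outside curve domain")
  list(mu = stats::approx(curve$calbp, curve$mu, t_bp)$y,
       sigma = stats::approx(curve$calbp, curve$sigma, t_bp)$y)
}

#' Smooth synthetic calibration-curve pair
#'
#' Deterministic wiggly curves used for simulation and testing: the
#' terrestrial curve tracks calendar age with multi-decadal wiggles; the
#' marine curve adds a global reservoir offset of ~430 14C yr and broader
#' uncertainty. Clearly synthetic; they are not SHCal20/Marine20.
#'
#' @param range_bp grid range in cal BP.
#' @param step grid step (yr).
#' @return list with `terrestrial` and `marine` [calcurve()]s.
#' @export
synthetic_calcurves <- function(range_bp = c(0, 3500), step = 5) {
  t <- seq(range_bp[1], range_bp[2], by = step)
  mu_t <- t + 35 * sin(2 * pi * t / 350) + 20 * sin(2 * pi * t / 93 + 1)
  mu_m <- t + 430 + 25 * sin(2 * pi * t / 310 + 0.5)
  list(terrestrial = calcurve(t, mu_t, rep(12, length(t)), "synthetic-terr"),
       marine = calcurve(t, mu_m, rep(20, length(t)), "synthetic-marine"))
}

#' Diet-weighted mixture of terrestrial and marine curves
#'
#' mean = (1-p) mu_T(t) + p (mu_M(t) + deltaR);
#' sigma^2 = (1-p)^2 sigma_T^2 + p^2 sigma_M^2.
#'
#' @param terr,marine [calcurve()] objects.
#' @param p_marine marine diet fraction in [0, 1].
#' @param deltaR local marine reservoir offset (14C yr).
#' @param t_bp calendar years (cal BP) at which to evaluate.
#' @return list with `mean` and `sigma`.
#' @export
mixed_curve <- function(terr, marine, p_marine, deltaR, t_bp) {
  if (any(p_marine < 0 | p_marine > 1))
    stop("invalid-argument: p_marine must be in [0,1]")
  a <- curve_at(terr, t_bp)
  b <- curve_at(marine, t_bp)
  list(mean = (1 - p_marine) * a$mu + p_marine * (b$mu + deltaR),
       sigma = sqrt((1 - p_marine)^2 * a$sigma^2 + p_marine^2 * b$sigma^2))
}

# log-likelihood of a measured 14C age at calendar years t_bp
c14_loglik <- function(c14_age, sigma_lab, curves, p_marine, deltaR, t_bp) {
  mx <- mixed_curve(curves$terrestrial, curves$marine, p_marine, deltaR, t_bp)
  stats::dnorm(c14_age, mx$mean, sqrt(mx$sigma^2 + sigma_lab^2), log = TRUE)
}

#' Calibrate a single radiocarbon determination
#'
#' Grid posterior over calendar years with a flat prior: density
#' proportional to Normal(age; mixed mean(t), sqrt(mixed sigma(t)^2 +
#' sigma_lab^2)), normalised to integrate to 1. The 95% HPD is found by
#' density thresholding.
#'
#' @param c14_age measured 14C age (BP).
#' @param sigma_lab laboratory sigma.
#' @param curves list with `terrestrial` and `marine` curves.
#' @param p_marine marine diet fraction.
#' @param deltaR reservoir offset.
#' @param prob HPD mass (default 0.95).
#' @return list: `calbp` grid, `density`, `median_bp`, `median_ce`,
#'   `hpd_bp` (matrix of intervals), `hpd_ce`.
#' @export
calibrate_single <- function(c14_age, sigma_lab, curves, p_marine = 0,
                             deltaR = 0, prob = 0.95) {
  grid <- curves$terrestrial$calbp
  grid <- grid[grid >= min(curves$marine$calbp) &
               grid <= max(curves$marine$calbp)]
  ll <- c14_loglik(c14_age, sigma_lab, curves, p_marine, deltaR, grid)
  w <- exp(ll - max(ll))
  step <- diff(grid[1:2])
  total <- sum(w) * step
  if (total <= 0 || !is.finite(total)) stop("zero posterior mass in domain")
  dens <- w / total
  cdf <- cumsum(dens) * step
  median_bp <- grid[which.min(abs(cdf - 0.5))]
  # HPD by descending-density inclusion
  o <- order(dens, decreasing = TRUE)
  mass <- cumsum(dens[o]) * step
  keep <- sort(o[seq_len(which(mass >= prob)[1])])
  brk <- c(0, which(diff(keep) > 1), length(keep))
  hpd <- t(vapply(seq_len(length(brk) - 1), function(b) {
    seg <- keep[(brk[b] + 1):brk[b + 1]]
    c(grid[min(seg)], grid[max(seg)])
  }, c(0, 0)))
  colnames(hpd) <- c("lo_bp", "hi_bp")
  list(calbp = grid, density = dens, median_bp = median_bp,
       median_ce = 1950 - median_bp, hpd_bp = hpd,
       hpd_ce = cbind(lo_ce = 1950 - hpd[, "hi_bp"],
                      hi_ce = 1950 - hpd[, "lo_bp"]))
}

#' Build a family chronological model
#'
#' Parameters are per-individual birth years and ages at death (within
#' ranges), one deposition year for the named members (deaths within a
#' tolerance window of it), and a free deltaR. Parent-child birth gaps from
#' the pedigree are constrained to a generational window. Determinations on
#' human tissue bind to birth + tissue age; context determinations
#' (individual NA) bind to the deposition year with marine fraction 0.
#'
#' @param dets determinations data.frame: lab_id, individual (NA = context),
#'   c14_age, sigma, tissue_age, marine_frac, and optionally marine_sd.
#' @param ped pedigree data.frame (edges among modeled individuals are used;
#'   may be NULL for an unconstrained model).
#' @param ages named list of c(lo, hi) age-at-death ranges per individual.
#' @param deposition_members character vector of ids whose deaths co-occur.
#' @param deltaR_prior c(lo, hi) uniform prior bounds (14C yr).
#' @param generation_gap c(lo, hi) allowed parent-child birth gap (yr).
#' @param deposition_tol half-width of the deposition window (yr).
#' @param curves list with `terrestrial` and `marine` curves.
#' @return object of class `family_model`.
#' @export
build_family_model <- function(dets, ped = NULL, ages,
                               deposition_members = character(0),
                               deltaR_prior = c(-600, 100),
                               generation_gap = c(12, 50),
                               deposition_tol = 5,
                               curves = synthetic_calcurves()) {
  ids <- unique(c(stats::na.omit(dets$individual), deposition_members))
  if (length(ids) == 0) stop("config-error: no modeled individuals")
  miss <- setdiff(stats::na.omit(dets$individual), names(ages))
  if (length(miss))
    stop("config-error: unmapped determination individual(s): ",
         paste(miss, collapse = ", "))
  edges <- NULL
  if (!is.null(ped)) {
    e <- rbind(
      data.frame(parent = ped$mother, child = ped$id, stringsAsFactors = FALSE),
      data.frame(parent = ped$father, child = ped$id, stringsAsFactors = FALSE))
    e <- e[!is.na(e$parent) & e$parent %in% ids & e$child %in% ids, ]
    edges <- e
  }
  if (is.null(dets$marine_sd)) dets$marine_sd <- 0.05
  structure(list(dets = dets, ids = ids, ages = ages, edges = edges,
                 deposition_members = deposition_members,
                 deltaR_prior = deltaR_prior,
                 generation_gap = generation_gap,
                 deposition_tol = deposition_tol,
                 curves = curves,
                 pre = precompute_curves(curves),
                 alo = vapply(ages[ids], function(r) r[1], 0),
                 ahi = vapply(ages[ids], function(r) r[length(r)], 0)),
            class = "family_model")
}

# regular-grid curve arrays for fast interpolation inside the sampler
precompute_curves <- function(curves) {
  tc <- curves$terrestrial; mc <- curves$marine
  t0 <- max(min(tc$calbp), min(mc$calbp))
  t1 <- min(max(tc$calbp), max(mc$calbp))
  step <- min(diff(tc$calbp[1:2]), diff(mc$calbp[1:2]), 5)
  grid <- seq(t0, t1, by = step)
  at <- function(cv) list(mu = stats::approx(cv$calbp, cv$mu, grid)$y,
                          sigma = stats::approx(cv$calbp, cv$sigma, grid)$y)
  a <- at(tc); b <- at(mc)
  list(t0 = t0, t1 = t1, step = step, n = length(grid),
       mu_t = a$mu, sig_t = a$sigma, mu_m = b$mu, sig_m = b$sigma)
}

# linear interpolation on the precomputed grid; returns NA outside domain
interp_pre <- function(pre, y, t_bp) {
  x <- (t_bp - pre$t0) / pre$step
  i <- floor(x)
  ok <- i >= 0 & i < pre$n - 1
  out <- rep(NA_real_, length(t_bp))
  fr <- x[ok] - i[ok]
  out[ok] <- y[i[ok] + 1] * (1 - fr) + y[i[ok] + 2] * fr
  out
}

# joint log-posterior of a parameter state (vectorised over determinations)
fm_logpost <- function(model, st) {
  gg <- model$generation_gap
  if (st["deltaR"] < model$deltaR_prior[1] ||
      st["deltaR"] > model$deltaR_prior[2]) return(-Inf)
  ages <- st[paste0("age_", model$ids)]
  if (any(ages < model$alo | ages > model$ahi)) return(-Inf)
  if (!is.null(model$edges) && nrow(model$edges)) {
    gap <- st[paste0("birth_", model$edges$child)] -
      st[paste0("birth_", model$edges$parent)]
    if (any(gap < gg[1] | gap > gg[2])) return(-Inf)
  }
  if (length(model$deposition_members)) {
    death <- st[paste0("birth_", model$deposition_members)] +
      st[paste0("age_", model$deposition_members)]
    if (any(abs(death - st["D"]) > model$deposition_tol)) return(-Inf)
  }
  d <- model$dets
  hum <- !is.na(d$individual)
  p <- numeric(nrow(d))
  t_ce <- numeric(nrow(d))
  t_ce[!hum] <- st["D"]
  if (any(hum)) {
    t_ce[hum] <- st[paste0("birth_", d$individual[hum])] + d$tissue_age[hum]
    p[hum] <- st[paste0("pmar_", which(hum))]
  }
  pre <- model$pre
  t_bp <- 1950 - t_ce
  mu_t <- interp_pre(pre, pre$mu_t, t_bp)
  if (anyNA(mu_t)) return(-Inf)
  mu_m <- interp_pre(pre, pre$mu_m, t_bp)
  s_t <- interp_pre(pre, pre$sig_t, t_bp)
  s_m <- interp_pre(pre, pre$sig_m, t_bp)
  mu <- (1 - p) * mu_t + p * (mu_m + st["deltaR"])
  sd_tot <- sqrt((1 - p)^2 * s_t^2 + p^2 * s_m^2 + d$sigma^2)
  lp <- sum(stats::dnorm(d$c14_age, mu, sd_tot, log = TRUE))
  if (any(hum))
    lp <- lp + sum(stats::dnorm(p[hum], d$marine_frac[hum],
                                pmax(d$marine_sd[hum], 1e-6), log = TRUE))
  lp
}

fm_init <- function(model, jitter = 0) {
  d <- model$dets
  curves <- model$curves
  gg <- model$generation_gap
  tol <- model$deposition_tol
  ctx <- d[is.na(d$individual), ]
  grid <- curves$terrestrial$calbp
  if (nrow(ctx)) {
    mu <- curve_at(curves$terrestrial, grid)$mu
    D_bp <- grid[which.min(abs(mu - mean(ctx$c14_age)))]
    D <- 1950 - D_bp
  } else D <- 500
  D <- D + jitter * stats::rnorm(1, 0, 5)
  ids <- model$ids
  dep <- intersect(model$deposition_members, ids)
  age <- vapply(model$ages[ids], mean, 0)
  names(age) <- ids
  alo <- model$alo; ahi <- model$ahi
  slack <- stats::setNames(rep(0, length(ids)), ids)  # within-tolerance shift
  # member deaths sit at D + slack; births follow from age. Repair
  # generation-gap violations by pushing parent ages up / child ages down
  # and using the deposition slack.
  birth_of <- function() {
    b <- D - age + slack
    # non-members: untie from D; place relative to their dated event or
    # their children further down
    b
  }
  if (!is.null(model$edges) && nrow(model$edges)) {
    for (rep in 1:30) {
      b <- birth_of()
      done <- TRUE
      for (k in seq_len(nrow(model$edges))) {
        p <- model$edges$parent[k]; ch <- model$edges$child[k]
        gap <- b[ch] - b[p]
        if (gap < gg[1] + 0.5) {
          need <- gg[1] + 0.5 - gap
          give <- min(need, ahi[p] - age[p])
          age[p] <- age[p] + give; need <- need - give
          if (need > 0) {
            give <- min(need, age[ch] - alo[ch])
            age[ch] <- age[ch] - give; need <- need - give
          }
          if (need > 0) {
            give <- min(need, tol - 0.2 + slack[p])
            slack[p] <- slack[p] - give; need <- need - give
          }
          if (need > 0) slack[ch] <- min(slack[ch] + need, tol - 0.2)
          done <- FALSE
        } else if (gap > gg[2] - 0.5) {
          age[p] <- max(age[p] - (gap - gg[2] + 0.5), alo[p])
          done <- FALSE
        }
      }
      if (done) break
    }
  }
  b <- birth_of()
  dR0 <- mean(model$deltaR_prior) + jitter * stats::rnorm(1, 0, 30)
  # non-members: centre on their own dated event when available
  hum <- d[!is.na(d$individual), ]
  for (i in setdiff(ids, dep)) {
    det_i <- hum[hum$individual == i, ]
    if (nrow(det_i)) {
      mu <- curve_at(curves$terrestrial, grid)$mu
      ev_bp <- grid[which.min(abs(mu - (det_i$c14_age[1] -
        det_i$marine_frac[1] * dR0)))]
      b[i] <- (1950 - ev_bp) - det_i$tissue_age[1]
    }
  }
  st <- c(D = D, deltaR = dR0)
  for (i in ids) {
    st[paste0("age_", i)] <- age[i]
    st[paste0("birth_", i)] <- b[i]
  }
  for (j in which(!is.na(d$individual)))
    st[paste0("pmar_", j)] <- min(max(d$marine_frac[j], 0.01), 0.99)
  st
}

#' Sample the family-model posterior
#'
#' Metropolis-within-Gibbs: scalar random-walk updates for every birth year,
#' age at death, the deposition year, deltaR, and each determination's
#' marine fraction (truncated-normal prior from its stated mean and sd).
#' Runs `n_chains` chains, reports split-Rhat for the deposition year and
#' deltaR, posterior medians, 95% HPDs and per-determination agreement
#' indices.
#'
#' @param model a [build_family_model()] object.
#' @param n_iter iterations per chain (after burn-in of the same length).
#' @param n_chains number of chains.
#' @param seed integer seed.
#' @param thin keep every `thin`-th draw.
#' @return list with `summary` (per-parameter median and HPD), `samples`,
#'   `rhat`, `converged`, `agreement` and the model.
#' @export
sample_posterior <- function(model, n_iter = 4000, n_chains = 2, seed = 1,
                             thin = 2) {
  set.seed(seed)
  d <- model$dets
  par0 <- fm_init(model)
  pnames <- names(par0)
  scales <- ifelse(grepl("^birth_", pnames), 12,
            ifelse(grepl("^age_", pnames), 2,
            ifelse(pnames == "D", 8,
            ifelse(pnames == "deltaR", 25, 0.05))))
  names(scales) <- pnames
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    st <- fm_init(model, jitter = 1)
    lp <- fm_logpost(model, st)
    tries <- 0
    while (!is.finite(lp) && tries < 50) {
      st <- fm_init(model, jitter = 0.2)
      lp <- fm_logpost(model, st)
      tries <- tries + 1
    }
    if (!is.finite(lp)) { st <- par0; lp <- fm_logpost(model, st) }
    if (!is.finite(lp)) stop("could not find a feasible starting state")
    total <- 2 * n_iter
    keep <- matrix(NA_real_, floor(n_iter / thin), length(pnames),
                   dimnames = list(NULL, pnames))
    krow <- 0
    for (it in seq_len(total)) {
      for (p in pnames) {
        prop <- st
        prop[p] <- st[p] + stats::rnorm(1, 0, scales[p])
        if (grepl("^pmar_", p)) {
          if (prop[p] < 0 || prop[p] > 1) next
        }
        lp2 <- fm_logpost(model, prop)
        if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
          st <- prop; lp <- lp2
        }
      }
      # joint translation of the whole chronology (deposition year and all
      # births together) decorrelates the event-time block
      prop <- st
      dlt <- stats::rnorm(1, 0, 6)
      sel <- c("D", paste0("birth_", model$ids))
      prop[sel] <- st[sel] + dlt
      lp2 <- fm_logpost(model, prop)
      if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
        st <- prop; lp <- lp2
      }
      if (it > n_iter && (it - n_iter) %% thin == 0) {
        krow <- krow + 1
        keep[krow, ] <- st
      }
    }
    chains[[ch]] <- keep[seq_len(krow), , drop = FALSE]
  }
  samples <- do.call(rbind, chains)
  rhat <- vapply(c("D", "deltaR"), function(p)
    split_rhat(lapply(chains, function(m) m[, p])), 0)
  summ <- t(apply(samples, 2, function(x)
    c(median = stats::median(x), hpd_interval(x, 0.95))))
  agreement <- fm_agreement(model, samples)
  list(summary = summ, samples = samples, rhat = rhat,
       converged = all(rhat < 1.05, na.rm = TRUE),
       agreement = agreement, model = model, n_chains = n_chains)
}

# split-Rhat over a list of chains
split_rhat <- function(chs) {
  halves <- unlist(lapply(chs, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 4) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# shortest interval containing `prob` mass of a sample
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1, floor(prob * n))
  if (k >= n) return(c(lo = x[1], hi = x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(lo = x[i], hi = x[i + k])
}

# OxCal-style agreement index per determination
fm_agreement <- function(model, samples) {
  d <- model$dets
  grid <- model$curves$terrestrial$calbp
  grid <- grid[grid >= min(model$curves$marine$calbp) &
               grid <= max(model$curves$marine$calbp)]
  step <- diff(grid[1:2])
  dR <- stats::median(samples[, "deltaR"])
  out <- data.frame(lab_id = d$lab_id, agreement = NA_real_,
                    pass60 = NA, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(d))) {
    if (is.na(d$individual[j])) {
      t_ce <- samples[, "D"]
      p <- 0
    } else {
      t_ce <- samples[, paste0("birth_", d$individual[j])] + d$tissue_age[j]
      p <- stats::median(samples[, paste0("pmar_", j)])
    }
    lik <- exp(c14_loglik(d$c14_age[j], d$sigma[j], model$curves, p, dR, grid))
    single <- lik / (sum(lik) * step)
    # posterior density of the event year from the samples, on the same grid
    t_bp <- pmin(pmax(1950 - t_ce, min(grid)), max(grid))
    h <- graphics::hist(t_bp, breaks = c(grid - step / 2, max(grid) + step / 2),
                        plot = FALSE)
    post <- h$density
    A <- 100 * sum(lik * post) / sum(lik * single)
    out$agreement[j] <- A
    out$pass60[j] <- A >= 60
  }
  out
}
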