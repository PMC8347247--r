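# Shared fixtures: repeatability tables, hand-built triplets, random triplet
# tables and an independent brute-force labeller used as oracle.

VARS <- kc_variables()
ALL_VARS <- kc_variables(include_age = TRUE)

default_rt <- function() compute_repeatability(default_sw())

# a repeatability table with the worked-example Kmax limit (r = 0.72 D)
worked_rt <- function() {
  repeatability_from_r(c(KmaxZonalMean3mm = 0.72, RsF = 0.1, BFSF = 0.1,
                         RmB = 0.1, LOGIK = 0.3))
}

# one-row triplet table from named per-slot value lists
make_triplet <- function(bl, f1, f2, eye_id = "E0001",
                         quality = c("OK", "OK", "OK")) {
  tr <- data.frame(eye_id = eye_id, window_index = 1L,
                   stringsAsFactors = FALSE)
  slots <- list(bl = bl, f1 = f1, f2 = f2)
  dates <- as.Date(c("2020-01-01", "2020-08-01", "2021-03-01"))
  for (i in seq_along(slots)) {
    s <- names(slots)[i]
    tr[[paste0("date_", s)]] <- dates[i]
    tr[[paste0("quality_", s)]] <- quality[i]
    for (v in ALL_VARS) tr[[paste(v, s, sep = "_")]] <- slots[[i]][[v]]
  }
  tr$label <- NA_character_
  tr$n_exceed <- NA_integer_
  class(tr) <- c("kc_triplets", "data.frame")
  tr
}

# flat exam values; every variable at a plausible magnitude
base_exam <- function() {
  c(Age = 30, KmaxZonalMean3mm = 48, RsF = 6.8, BFSF = 7.8, RmB = 6.4,
    LOGIK = 1.5)
}

# the single-variable worked example: Kmax (44, 43.5, 45) D, everything else
# flat so only Kmax can trigger
worked_triplet <- function() {
  e <- base_exam()
  bl <- f1 <- f2 <- as.list(e)
  bl$KmaxZonalMean3mm <- 44
  f1$KmaxZonalMean3mm <- 43.5
  f2$KmaxZonalMean3mm <- 45
  f1$Age <- 30.6
  f2$Age <- 31.2
  make_triplet(bl, f1, f2)
}

# n random triplets with follow-up deltas spanning all three noise-reduction
# branches of every variable
random_triplets <- function(n, rt, seed = 1) {
  set.seed(seed)
  tr <- data.frame(eye_id = sprintf("E%05d", seq_len(n)), window_index = 1L,
                   stringsAsFactors = FALSE)
  e <- base_exam()
  for (s in c("bl", "f1", "f2")) {
    tr[[paste0("quality_", s)]] <- "OK"
    for (v in ALL_VARS) {
      base <- rep(e[[v]], n)
      if (s == "bl") {
        tr[[paste(v, s, sep = "_")]] <- base + rnorm(n, 0, 0.1 * e[[v]])
      } else if (v == "Age") {
        off <- if (s == "f1") 0.7 else 1.4
        tr[[paste(v, s, sep = "_")]] <- tr[[paste(v, "bl", sep = "_")]] + off
      } else {
        r_v <- rt$r[rt$variable == v]
        # deltas up to +/- 3 r so all branches occur
        tr[[paste(v, s, sep = "_")]] <- tr[[paste(v, "bl", sep = "_")]] +
          runif(n, -3 * r_v, 3 * r_v)
      }
    }
  }
  tr$label <- NA_character_
  tr$n_exceed <- NA_integer_
  class(tr) <- c("kc_triplets", "data.frame")
  tr
}

# Independent brute-force labeller: enumerates the five variables and both
# directions case by case. Intentionally scalar and naive.
oracle_label <- function(triplets, rt) {
  out_label <- character(nrow(triplets))
  out_count <- integer(nrow(triplets))
  for (i in seq_len(nrow(triplets))) {
    count <- 0L
    for (v in VARS) {
      r_v <- rt$r[rt$variable == v]
      dir_v <- rt$direction[rt$variable == v]
      bl <- triplets[[paste0(v, "_bl")]][i]
      f2 <- triplets[[paste0(v, "_f2")]][i]
      if (dir_v == "INCREASING") {
        if (f2 - bl > r_v) count <- count + 1L
      } else {
        if (bl - f2 > r_v) count <- count + 1L
      }
    }
    out_count[i] <- count
    out_label[i] <- if (count >= 1L) "SUSPECT_PROGRESSIVE" else "STABLE"
  }
  list(label = out_label, n_exceed = out_count)
}

# drift at `mult` repeatability limits per visit in the clinical direction
strong_drift <- function(mult = 3, sw = default_sw()) {
  rt <- compute_repeatability(sw)
  drift <- mult * rt$r * ifelse(rt$direction == "INCREASING", 1, -1)
  names(drift) <- rt$variable
  drift
}

# clean cohort spec (no quality contamination, no severe cases)
clean_spec <- function(n_eyes, visits = 3L, progressive_fraction = 0,
                       drift_mult = 3, noise = default_sw(), seed = 1) {
  cohort_spec(
    n_eyes = n_eyes, visits_per_eye = visits,
    progressive_fraction = progressive_fraction,
    drift_per_visit = strong_drift(drift_mult),
    noise_table = noise,
    p_yellow = 0, p_red = 0, p_severe = 0, seed = seed
  )
}

fast_config <- function(...) {
  training_config(n_hidden = 5L, max_epochs = 30L, ...)
}
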