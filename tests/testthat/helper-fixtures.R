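# Shared, lazily computed fixtures. The desk-scale study conditions used
# throughout the suite: paired gel/dry sessions with 40/40/22/45-s segments,
# 60 VEP reversals, 500 Hz, defaults otherwise.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

desk_config <- function(n_subjects = 3, seed = 42, ...) {
  sim_config(n_subjects = n_subjects, seed = seed,
             segment_durations = c(eyes_open = 40, eyes_closed = 40,
                                   blink = 22, vep = 45),
             n_vep_epochs = 60, ...)
}

fix_combined <- function() {
  memo("combined", combined_layout(builtin_layout("ten_twenty"),
                                   builtin_layout("equidistant")))
}

fix_cohort <- function() memo("cohort", simulate_cohort(desk_config()))

fix_cohort_analysis <- function() {
  memo("cohort_analysis", analyze_cohort(fix_cohort(), fix_combined()))
}

# n = 10 cohort used by the parameter-recovery and direction checks
fix_big_cohort <- function() {
  memo("big_cohort", simulate_cohort(desk_config(n_subjects = 10, seed = 1)))
}

fix_big_cohort_analysis <- function() {
  memo("big_cohort_analysis", analyze_cohort(fix_big_cohort(),
                                             fix_combined()))
}

# independent two-sided Mann-Whitney p by full enumeration of all
# C(na+nb, na) group assignments of the pooled sample
mwu_enum_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# degree-2 zonal spherical harmonic, the smooth benchmark field
y20_field <- function(pos) 0.5 * (3 * pos[, 3]^2 - 1)
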