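# Study-design sampling times and small TAC builders used across tests.

design_times <- c(0.5, 4, 24, 72)

mono_tac <- function(a0 = 100, lambda = 0.02, times = design_times) {
  tibble::tibble(time_h = times, activity_mbq = a0 * exp(-lambda * times))
}

biorigin_tac <- function(a0 = 200, lw = 0.01, lu = 0.5, times = design_times) {
  tibble::tibble(time_h = times,
                 activity_mbq = a0 * (exp(-lw * times) - exp(-lu * times)))
}

# All permutations of 1:n (recursive enumeration; tiny n only).
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Numeric quadrature of a composite curve over a finite window — the
# independent oracle for closed-form integration. Integrates each smooth
# piece separately (the composite curve may have kinks or jumps at
# segment boundaries, which adaptive quadrature handles poorly).
quadrature_tia <- function(pw, horizon) {
  cuts <- sort(unique(c(0, pw$segments$t_start, pw$segments$t_end, horizon)))
  cuts <- cuts[is.finite(cuts) & cuts <= horizon]
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    total <- total + stats::integrate(
      function(t) eval_curve(pw, t), cuts[i], cuts[i + 1],
      rel.tol = 1e-12, subdivisions = 500L
    )$value
  }
  total
}
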