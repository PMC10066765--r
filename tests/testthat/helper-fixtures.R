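# shared fixtures: built once per test run, all generated in code

TRUTH <- default_truth()

# generic small parameter set for property checks, away from the defaults
toy_pk <- function() {
  pk_params(tvCL12 = 10, tvCL23 = 0.5, tvCL32 = 2, tvCL20 = 0.3,
            tvV = 2, tvV2 = 1, cl_alpha = 0.631, cl_beta = 1.1,
            v_exponent = 1, wt_ref = 1)
}

toy_pd <- function() {
  pd_params(ke0 = 0.1, ksyn_slope = 0.05, kdeg = 0.03, kq = 0.005)
}

# independent reference solution of the piecewise-constant linear system
# via Matrix::expm with the augmented-matrix integral trick
expm_reference <- function(A, init, doses, times) {
  n <- nrow(A)
  stepx <- function(x, u, dt) {
    if (dt <= 0) return(x)
    Aug <- rbind(cbind(A * dt, u * dt), 0)
    E <- as.matrix(Matrix::expm(Matrix::Matrix(Aug)))
    E[1:n, 1:n] %*% x + E[1:n, n + 1]
  }
  ev <- data.frame(time = c(doses$time, doses$time + doses$duration))
  brk <- sort(unique(c(0, ev$time, times)))
  x <- matrix(init, ncol = 1)
  b0 <- doses$duration == 0 & doses$time < 1e-12
  if (any(b0)) x[1] <- x[1] + sum(doses$amount[b0])
  out <- matrix(NA_real_, length(times), n)
  hit <- function(t) which(abs(times - t) < 1e-12)
  if (length(hit(0))) out[hit(0), ] <- rep(drop(x), each = length(hit(0)))
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    u <- numeric(n)
    act <- doses$duration > 0 & doses$time <= t0 + 1e-12 &
      doses$time + doses$duration >= t1 - 1e-12
    if (any(act)) u[1] <- sum(doses$amount[act] / doses$duration[act])
    x <- stepx(x, u, t1 - t0)
    bol <- doses$duration == 0 & abs(doses$time - t1) < 1e-12
    if (any(bol)) x[1] <- x[1] + sum(doses$amount[bol])
    if (length(hit(t1))) out[hit(t1), ] <- rep(drop(x), each = length(hit(t1)))
  }
  out
}

rate_list <- function(k12, k23, k32, k20, V = 1, V2 = 1) {
  list(k12 = k12, k23 = k23, k32 = k32, k20 = k20, V = V, V2 = V2,
       CL12 = k12 * V, CL23 = k23 * V2, CL32 = k32 * V, CL20 = k20 * V2)
}
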