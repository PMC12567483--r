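# shared fixtures: reference SMILES, extdata paths, toy geometry builders

smi_l2129 <- "N[C@@H](Cc1cc(F)c(F)cc1F)CC(=O)N/N=C/c1ccc(F)c(F)c1"
smi_l2123 <- "N[C@@H](Cc1cc(F)c(F)cc1F)CC(=O)N/N=C/c1ccc(OC)c(OC)c1"
smi_sita <- "Fc1cc(c(F)cc1F)C[C@@H](N)CC(=O)N1CCn2c(nnc2C(F)(F)F)C1"

extdata <- function(name) {
  p <- system.file("extdata", name, package = "glucotriage")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", name)
  p
}

# random rigid pose of n atoms within a box, fixed elements
toy_pose <- function(n = 5, elements = NULL, ea = -7, seed = NULL, run = 1L,
                     index = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(elements)) elements <- rep("C", n)
  pose(matrix(stats::runif(3 * n, -5, 5), n), elements, ea = ea,
       run = run, index = index)
}

# regular hexagon pose (benzene-like) in the xy-plane
hexagon_pose <- function(center = c(0, 0, 0), radius = 1.39, ea = -7,
                         perm = 1:6) {
  ang <- 2 * pi * (0:5) / 6
  xyz <- cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
               center[3])
  b <- data.frame(a1 = 1:6, a2 = c(2:6, 1))
  pose(xyz[perm, , drop = FALSE], rep("C", 6), ea = ea,
       bonds = data.frame(a1 = match(b$a1, perm), a2 = match(b$a2, perm)))
}

# independent textbook Pearson correlation (direct-formula oracle)
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# independent desirability oracle: direct breakpoint arithmetic
mpo_oracle <- function(vals, lims, weights = rep(1, 6)) {
  ramp <- function(x, thr, zero) {
    if (x <= thr) 1 else if (x >= zero) 0 else (zero - x) / (zero - thr)
  }
  hump <- function(x, b) {
    if (x <= b[1] || x >= b[4]) 0
    else if (x >= b[2] && x <= b[3]) 1
    else if (x < b[2]) (x - b[1]) / (b[2] - b[1])
    else (b[4] - x) / (b[4] - b[3])
  }
  Tk <- c(ramp(vals[["logp"]], lims$logp[1], lims$logp[2]),
          ramp(vals[["logd74"]], lims$logd74[1], lims$logd74[2]),
          ramp(vals[["mw"]], lims$mw[1], lims$mw[2]),
          hump(vals[["tpsa"]], lims$tpsa),
          ramp(vals[["hbd"]], lims$hbd[1], lims$hbd[2]),
          ramp(vals[["pka_basic"]], lims$pka_basic[1], lims$pka_basic[2]))
  sum(weights * Tk)
}

default_lims <- list(logp = c(3, 5), logd74 = c(2, 4), mw = c(360, 500),
                     tpsa = c(20, 40, 90, 120), hbd = c(1, 3.5),
                     pka_basic = c(8, 10))
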