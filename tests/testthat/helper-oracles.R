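# Independent oracles, deliberately written as naive loops so they share no
# code path with the implementation they check.

# per-label mean and population s.d. by explicit pixel loop
oracle_granularity <- function(img, mask) {
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  out <- data.frame(label = labs, mean_intensity = NA_real_,
                    intensity_sd = NA_real_)
  for (k in seq_along(labs)) {
    vals <- c()
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
      if (mask[i, j] == labs[k]) vals <- c(vals, img[i, j])
    m <- sum(vals) / length(vals)
    out$mean_intensity[k] <- m
    out$intensity_sd[k] <- sqrt(sum((vals - m)^2) / length(vals))
  }
  out
}

# all-pairs heavy-atom distance loop over a toy system
oracle_contacts <- function(top, coords, ligand, cutoff, box = NULL) {
  heavy <- !(toupper(top$element) %in% c("H", "D"))
  lig <- which(top$resname == ligand & heavy)
  prot <- which(top$resname != ligand & heavy)
  resids <- sort(unique(top$resno[prot]))
  nf <- dim(coords)[1]
  out <- matrix(FALSE, nf, length(resids))
  for (f in seq_len(nf)) {
    for (ri in seq_along(resids)) {
      atoms <- prot[top$resno[prot] == resids[ri]]
      hit <- FALSE
      for (a in atoms) for (l in lig) {
        dd <- coords[f, a, ] - coords[f, l, ]
        if (!is.null(box)) dd <- dd - box * round(dd / box)
        if (sqrt(sum(dd^2)) <= cutoff) { hit <- TRUE; break }
      }
      out[f, ri] <- hit
    }
  }
  out
}

# OLS coefficients via explicit normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# nuclei records with a given s.d.-vs-mean slope, for the granularity model
gen_records <- function(slope, n, grp, seed, sd_noise = 40, reps = 2) {
  set.seed(seed)
  mi <- runif(n, 500, 3000)
  data.frame(mean_intensity = mi,
             intensity_sd = 50 + slope * mi + rnorm(n, 0, sd_noise),
             group = grp, replicate = rep(seq_len(reps), length.out = n))
}

# random toy topology/coordinate system for contact-matrix checks
random_toy_system <- function(seed, n_res = 4, atoms_per_res = 3,
                              n_lig = 3, n_frames = 5, box = NULL) {
  set.seed(seed)
  n_prot <- n_res * atoms_per_res
  el <- sample(c("C", "N", "O", "H"), n_prot + n_lig, replace = TRUE)
  el[n_prot + 1L] <- "C"  # ligand always has at least one heavy atom
  top <- data.frame(
    resno = c(rep(seq_len(n_res), each = atoms_per_res),
              rep(n_res + 1L, n_lig)),
    resname = c(rep("ALA", n_prot), rep("LIG", n_lig)),
    name = paste0("A", seq_len(n_prot + n_lig)),
    element = el)
  span <- if (is.null(box)) 15 else box[1]
  coords <- array(runif(n_frames * (n_prot + n_lig) * 3, 0, span),
                  c(n_frames, n_prot + n_lig, 3))
  list(top = top, coords = coords)
}
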