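# shared fixtures: hand-built scenes, a small simulated trial, the printed
# variety yield means, and an independent brute-force GLCM oracle

# five-band scene from one matrix (all bands identical unless overridden)
toy_scene <- function(m, date = "2021-05-01", gsd = 1,
                      origin = NULL, bands = NULL) {
  if (is.null(bands))
    bands <- list(BLUE = m, GREEN = m, RED = m, REDEDGE = m, NIR = m)
  if (is.null(origin)) origin <- c(0, nrow(bands[[1]]) * gsd)
  scene(date, bands, gsd, origin)
}

# rectangle ROI covering pixel centers [r1..r2] x [c1..c2] of a toy scene
toy_roi <- function(r1, r2, c1, c2, gsd = 1, nrow_m = NULL, id = "P1") {
  # toy_scene origin puts y = nrow(m) at the top; pixel r center y = nrow - (r-0.5)
  ytop <- nrow_m - (r1 - 1) * gsd
  ybot <- nrow_m - r2 * gsd
  poly <- cbind(c((c1 - 1) * gsd, c2 * gsd, c2 * gsd, (c1 - 1) * gsd),
                c(ytop, ytop, ybot, ybot))
  plot_roi(id, "V01", 1, 2021, poly)
}

# small trial used by several suites (6 varieties x 2 reps, 5 dates)
small_trial <- function(seed = 1, render = TRUE, n_dates = 5) {
  simulate_trial(sim_config(seed = seed, n_varieties = 6, n_reps = 2,
                            schedule = seq(400, 1400,
                                           length.out = n_dates)),
                 render = render)
}

# printed mean plot yields (g/m2) per variety and year
variety_means_2021 <- c(
  Absalon = 532.0, Aurelius = 541.9, Axioma = 473.0, Bernstein = 522.3,
  Bologna = 490.7, `CH-Nara` = 559.4, Chevignon = 598.5, Costello = 478.6,
  Dagmar = 617.1, Elixer = 540.4, Hyvento = 576.2, Julie = 544.2,
  Julius = 443.3, Montalbano = 584.1, `Mv Nador` = 552.4, Nogal = 504.2,
  `RGT-Reform` = 411.4, Rumor = 543.9, Skyfall = 642.7)

variety_means_2022 <- c(
  Absalon = 700.8, Aurelius = 759.7, Axioma = 631.0, Bernstein = 625.0,
  Bologna = 660.7, `CH-Nara` = 683.2, Chevignon = 672.5, Costello = 589.0,
  Dagmar = 725.2, Elixer = 721.3, Hyvento = 685.3, Julie = 661.8,
  Julius = 544.0, Montalbano = 681.1, `Mv Nador` = 591.9, Nogal = 557.8,
  `RGT-Reform` = 671.6, Skyfall = 773.2)

# ---- independent GLCM oracle: exhaustive pair enumeration ----------------

oracle_glcm_window <- function(win, nlev, dr, dc) {
  P <- matrix(0, nlev, nlev)
  nr <- nrow(win); nc <- ncol(win)
  for (r in 1:nr) for (c in 1:nc) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- win[r, c] + 1; j <- win[r2, c2] + 1
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  }
  P / sum(P)
}

oracle_features <- function(P) {
  n <- nrow(P)
  con <- dis <- ene <- hom <- 0
  mu <- 0
  for (i in 1:n) for (j in 1:n) mu <- mu + P[i, j] * (i - 1)
  v <- 0
  for (i in 1:n) for (j in 1:n) v <- v + P[i, j] * (i - 1 - mu)^2
  corsum <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]
    con <- con + p * (i - j)^2
    dis <- dis + p * abs(i - j)
    ene <- ene + p^2
    hom <- hom + p / (1 + (i - j)^2)
    corsum <- corsum + p * (i - 1 - mu) * (j - 1 - mu)
  }
  c(CON = con, COR = if (v > 1e-12) corsum / v else 0,
    DIS = dis, ENE = ene, HOM = hom)
}

# full-raster oracle: per interior pixel, enumerate all three directions
oracle_texture_rasters <- function(q, nlev, kernel = 5) {
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0))
  h <- kernel %/% 2
  nr <- nrow(q); nc <- ncol(q)
  out <- lapply(1:5, function(i) matrix(NA_real_, nr, nc))
  names(out) <- c("CON", "COR", "DIS", "ENE", "HOM")
  for (r in (h + 1):(nr - h)) for (c in (h + 1):(nc - h)) {
    win <- q[(r - h):(r + h), (c - h):(c + h)]
    if (anyNA(win)) next
    fs <- sapply(offsets, function(o)
      oracle_features(oracle_glcm_window(win, nlev, o[1], o[2])))
    m <- rowMeans(fs)
    for (f in names(out)) out[[f]][r, c] <- m[[f]]
  }
  out
}

# wrap a feature matrix in an existing scene's geometry
scene_band <- function(scn, m) {
  scn$bands <- list(FEAT = m)
  scn
}
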