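# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# flat RGB array filled with one colour
solid_rgb <- function(h, w, rgb) {
  px <- array(0L, c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  px
}

# write a PNG slide fixture and open it
png_slide <- function(px, base_magnification = 40) {
  path <- tempfile(fileext = ".png")
  png::writePNG(px / 255, path)
  open_slide(path, base_magnification = base_magnification)
}

# tiny deterministic cohort for training tests
tiny_cohort <- function(n_patients = 14, nodes = c(10, 18), feature_dim = 32,
                        beta_true = 2, seed = 5) {
  simulate_cohort(cohort_sim_config(
    n_patients = n_patients, slides_per_patient = c(1, 2),
    nodes_per_graph = nodes, feature_dim = feature_dim,
    signal_dim_count = 8, beta_true = beta_true, seed = seed))
}

tiny_backbone <- function(arch = "gcn", pooling = "kde", dropout = 0) {
  backbone_config(arch, hidden_dims = c(16L, 8L), embed_dim = 8L,
                  gat_heads = 2L, dropout = dropout, pooling = pooling,
                  kde_grid = 4L)
}

# pure-R flood-fill labelling oracle (queue-based), used to validate the
# compiled component labelling
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || lab[rr, cc] != 0L) next
    cur <- cur + 1L
    queue <- list(c(rr, cc)); lab[rr, cc] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[d, 1]; c2 <- p[2] + nb[d, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# brute-force Harrell concordance oracle
cindex_oracle <- function(risks, times, events) {
  conc <- 0; comp <- 0
  n <- length(risks)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !events[i] || times[i] >= times[j]) next
    comp <- comp + 1
    if (risks[i] > risks[j]) conc <- conc + 1
    else if (risks[i] == risks[j]) conc <- conc + 0.5
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}
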