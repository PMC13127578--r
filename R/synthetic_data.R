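# Deterministic construct sequence with a known grid of reactive residues:
# on a 20-residue period, position 3 is K, 5 is S, 9 is T, 13 is Y; filler
# cycles through non-reactive residues. Gives dense, predictable K/S/T/Y
# placement for planting links and ambiguity decoys (each K at 20k+3 has an
# S two residues downstream at 20k+5).
make_sequence <- function(n) {
  filler <- strsplit("ALGVEDRINQFHPWMC", "")[[1]]
  out <- filler[(seq_len(n) - 1L) %% length(filler) + 1L]
  pos <- seq_len(n)
  out[pos %% 20L == 3L] <- "K"
  out[pos %% 20L == 5L] <- "S"
  out[pos %% 20L == 9L] <- "T"
  out[pos %% 20L == 13L] <- "Y"
  paste(out, collapse = "")
}

# multiplicative log-normal noise with unit mean and coefficient of
# variation cv (cv = 0 gives exactly 1)
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate a two-condition qXL-MS quantification table with known truth
#'
#' Emulates the design of a three-replicate, two-condition label-free
#' qXL-MS experiment: MS1 intensities drawn log-normally around condition
#' means scaled by planted fold changes and per-replicate loading factors;
#' unreacted "carrier" peptides so the normalization denominator exists; a
#' declared fraction of peptides carrying ambiguous candidate sites; and a
#' mixture of interpeptide/intrapeptide cross-links and monolinks across a
#' heavy-chain-sized and a light-chain-sized construct. Each link is
#' observed as two peptide species (charges 2 and 3) so aggregation is
#' always exercised.
#'
#' @param n_links Number of link species (>= 1).
#' @param n_replicates Replicates per condition (default 3).
#' @param log2_effects Planted log2 fold changes (treated/control): a
#'   vector recycled to `n_links` (default all 0).
#' @param cv Coefficient of variation of multiplicative log-normal noise
#'   (default 0.1; 0 = noise-free).
#' @param loading_factors Per-replicate loading multipliers, a numeric
#'   vector of length `2 * n_replicates` ordered control replicates then
#'   treated replicates (default all 1).
#' @param kind_probs Mixture over link kinds, named
#'   (`interpeptide`, `intrapeptide`, `monolink`).
#' @param ambiguous_fraction Fraction of cross-linked peptide rows carrying
#'   an ambiguous candidate site (an S/T decoy near the true K; default 0).
#' @param n_carrier Number of unreacted carrier peptides (default 150).
#' @param seed Integer seed; identical seeds reproduce the table
#'   bit-for-bit.
#' @param emit_dir If non-`NULL`, also writes `quant.csv` and
#'   `constructs.fasta` there.
#' @return List: `peptides` (`xlms_peptides` table), `sequences` (named
#'   character), `truth` (`data.frame`: `link`, `link_kind`, `log2fc`),
#'   `conditions` (`c("control", "treated")`), `loading_factors`, `cv`,
#'   `seed`.
#' @export
simulate_quant_dataset <- function(n_links, n_replicates = 3,
                                   log2_effects = 0, cv = 0.1,
                                   loading_factors = NULL,
                                   kind_probs = c(interpeptide = 0.4,
                                                  intrapeptide = 0.3,
                                                  monolink = 0.3),
                                   ambiguous_fraction = 0,
                                   n_carrier = 150,
                                   seed = 1, emit_dir = NULL) {
  stopifnot(n_links >= 1, n_replicates >= 2)
  if (cv < 0) stop("cv must be non-negative")
  set.seed(seed)
  conditions <- c("control", "treated")
  if (is.null(loading_factors)) loading_factors <- rep(1, 2 * n_replicates)
  stopifnot(length(loading_factors) == 2 * n_replicates,
            all(loading_factors > 0))
  lf <- matrix(loading_factors, nrow = 2, byrow = TRUE,
               dimnames = list(conditions, paste0("R", seq_len(n_replicates))))

  log2fc <- rep_len(log2_effects, n_links)
  kinds <- sample(names(kind_probs), n_links, replace = TRUE,
                  prob = kind_probs)
  n_mono <- sum(kinds == "monolink")
  n_intra <- sum(kinds == "intrapeptide")
  n_inter <- sum(kinds == "interpeptide")

  # construct sizes scale with the simulation so distinct K sites exist
  # for every monolink and intrapeptide link (K every 20 residues)
  heavy_len <- max(1200L, 20L * (n_mono + n_intra + 60L))
  light_len <- max(300L, 20L * ceiling(sqrt(n_inter) + 15))
  sequences <- c(HCHAIN = make_sequence(heavy_len),
                 LCHAIN = make_sequence(light_len))
  kh <- sample(seq_len(heavy_len)[seq_len(heavy_len) %% 20L == 3L])
  kl <- seq_len(light_len)[seq_len(light_len) %% 20L == 3L]

  # unique heavy K sites for monolinks and intrapeptide anchors
  sa <- integer(n_links); sb <- rep(NA_integer_, n_links)
  pa <- rep("HCHAIN", n_links); pb <- rep(NA_character_, n_links)
  idx_mono <- which(kinds == "monolink")
  idx_intra <- which(kinds == "intrapeptide")
  idx_inter <- which(kinds == "interpeptide")
  sa[idx_mono] <- kh[seq_len(n_mono)]
  sa[idx_intra] <- kh[n_mono + seq_len(n_intra)]
  sb[idx_intra] <- ifelse(sa[idx_intra] + 20L <= heavy_len,
                          sa[idx_intra] + 20L, sa[idx_intra] - 20L)
  pb[idx_intra] <- "HCHAIN"
  # interpeptide links: unique (heavy, light) pairs drawn from the grid
  kh_rest <- kh[-(seq_len(n_mono + n_intra))]
  if (n_inter > length(kh_rest) * length(kl)) {
    stop("not enough reactive-site pairs for n_links; increase n_links budget")
  }
  cells <- sample(length(kh_rest) * length(kl), n_inter)
  sa[idx_inter] <- kh_rest[(cells - 1L) %% length(kh_rest) + 1L]
  sb[idx_inter] <- kl[(cells - 1L) %/% length(kh_rest) + 1L]
  pb[idx_inter] <- "LCHAIN"

  base <- stats::rlnorm(n_links, meanlog = log(1e6), sdlog = 0.8)
  n_amb_target <- round(ambiguous_fraction * n_links)
  amb <- rep(FALSE, n_links)
  if (n_amb_target > 0) {
    pool <- which(kinds != "monolink")
    amb[pool[seq_len(min(n_amb_target, length(pool)))]] <- TRUE
  }
  pep_end <- ifelse(kinds == "intrapeptide", sb, sa) + 4L
  peptide <- substr(rep(sequences["HCHAIN"], n_links),
                    pmax(1L, sa - 4L), pmin(heavy_len, pep_end))

  # expand to rows: link x species(2) x condition(2) x replicate
  R <- n_replicates
  li <- rep(seq_len(n_links), each = 4L * R)
  sp <- rep(rep(1:2, each = 2L * R), times = n_links)
  ci <- rep(rep(1:2, each = R), times = 2L * n_links)
  ri <- rep(seq_len(R), times = 4L * n_links)
  shares <- c(0.65, 0.35)
  mu <- base[li] * shares[sp] * ifelse(ci == 2L, 2^log2fc[li], 1)
  intensity <- mu * lf[cbind(ci, ri)] * lnoise(length(li), cv)
  link_rows <- data.frame(
    protein_a = pa[li], site_a = sa[li], protein_b = pb[li], site_b = sb[li],
    link_kind = kinds[li], peptide = peptide[li], charge = sp + 1L,
    condition = conditions[ci], replicate = paste0("R", ri),
    intensity = intensity, retention_time = NA_real_,
    candidate_sites = ifelse(amb[li] & sp == 1L, as.character(sa[li] + 2L),
                             NA_character_),
    stringsAsFactors = FALSE)

  # unreacted carrier peptides: loading-factor bearers for normalization
  cbase <- stats::rlnorm(n_carrier, meanlog = log(5e6), sdlog = 0.5)
  cstart <- ((seq_len(n_carrier) - 1L) %% 100L) * 11L + 1L
  cj <- rep(seq_len(n_carrier), each = 2L * R)
  cci <- rep(rep(1:2, each = R), times = n_carrier)
  cri <- rep(seq_len(R), times = 2L * n_carrier)
  carrier_rows <- data.frame(
    protein_a = "HCHAIN", site_a = NA_integer_,
    protein_b = NA_character_, site_b = NA_integer_,
    link_kind = "unreacted",
    peptide = substr(rep(sequences["HCHAIN"], n_carrier),
                     cstart, cstart + 9L)[cj],
    charge = 2L, condition = conditions[cci], replicate = paste0("R", cri),
    intensity = cbase[cj] * lf[cbind(cci, cri)] * lnoise(length(cj), cv),
    retention_time = NA_real_, candidate_sites = NA_character_,
    stringsAsFactors = FALSE)

  peptides <- rbind(link_rows, carrier_rows)
  rownames(peptides) <- NULL
  class(peptides) <- c("xlms_peptides", "data.frame")
  truth <- data.frame(link = link_key(pa, sa, pb, sb), link_kind = kinds,
                      log2fc = log2fc, ambiguous = amb,
                      stringsAsFactors = FALSE)

  if (!is.null(emit_dir)) {
    dir.create(emit_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(peptides, file.path(emit_dir, "quant.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    writeLines(paste0(">", names(sequences), "\n", unname(sequences)),
               file.path(emit_dir, "constructs.fasta"))
  }
  list(peptides = peptides, sequences = sequences, truth = truth,
       conditions = conditions, loading_factors = lf, cv = cv, seed = seed)
}

# idealized alpha-helical Calpha trace: radius 2.3 A, rise 1.5 A/residue,
# 100 degrees/residue, axis along `axis` from `origin`
helix_trace <- function(n, origin = c(0, 0, 0), axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame around the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  t <- (seq_len(n) - 1L)
  ang <- t * 100 * pi / 180
  pts <- outer(t * 1.5, axis) + 2.3 * (outer(cos(ang), u) + outer(sin(ang), v))
  sweep(pts, 2, origin, `+`)
}

rotmat_about <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * cos(a) + sin(a) * ux + (1 - cos(a)) * (u %*% t(u))
}

#' Generate a two-arm hinge structure pair with a planted rotation
#'
#' Builds two models of a single-chain "motor + lever" toy: a fixed
#' alpha-helical motor arm and a lever arm that, in the second model, is
#' rotated by `angle_deg` about a hinge axis through the arm junction —
#' a minimal stand-in for a lever swing between two conformations of a
#' motor domain. Every fifth residue is a lysine (cross-linkable); the
#' rest are alanines. A separate calibration chain `X` holds two Calpha
#' atoms exactly 30 Angstrom apart, probing the reach boundary. Ground
#' truth (the planted angle and a table of Calpha pair distances spanning
#' the 30 Angstrom boundary, recomputed from the emitted coordinates) is
#' returned alongside.
#'
#' @param angle_deg Hinge rotation in degrees, in [0, 180].
#' @param n_per_arm Residues per arm (>= 4; default 60, comparable to the
#'   ~9 nm helical span of a myosin lever, which keeps small rotations
#'   well-determined under coordinate noise).
#' @param coord_noise_sd Isotropic Gaussian noise (Angstrom) added to every
#'   coordinate of both models (default 0).
#' @param seed Seed for the noise draw.
#' @param emit_dir If non-`NULL`, writes `hinge_ref.pdb` / `hinge_rot.pdb`.
#' @return List: `model_a`, `model_b` (`xlms_model`s, chain `A` residues
#'   `1..2*n_per_arm` + chain `X`), `truth` (list: `angle_deg`,
#'   `hinge_axis`, `pairs` data.frame with per-model distances,
#'   `lysines`), `align_selection`, `segment_selection`.
#' @export
generate_toy_hinge <- function(angle_deg, n_per_arm = 60,
                               coord_noise_sd = 0, seed = 1,
                               emit_dir = NULL) {
  stopifnot(angle_deg >= 0, angle_deg <= 180)
  if (n_per_arm < 4) stop("n_per_arm must be at least 4")
  set.seed(seed)
  n <- n_per_arm
  # Each arm is L-shaped (two perpendicular helical legs) so that every
  # rotational degree of freedom of the arm is geometrically
  # well-conditioned; a single straight helix leaves twist about its own
  # axis constrained only by the 2.3 A helical radius.
  n1 <- ceiling(n / 2); n2 <- n - n1
  arm <- function(origin, axis1, axis2) {
    leg1 <- helix_trace(n1, origin = origin, axis = axis1)
    if (n2 == 0L) return(leg1)
    leg2 <- helix_trace(n2, origin = leg1[n1, ] + 1.5 * axis2, axis = axis2)
    rbind(leg1, leg2)
  }
  motor <- arm(c(0, 0, -1.5 * n1), c(0, 0, 1), c(0, -1, 0))
  lever0 <- arm(c(0, 0, 1.5), c(0, 0, 1), c(0, 1, 0))
  hinge_axis <- c(1, 0, 0)
  rot <- rotmat_about(hinge_axis, angle_deg)
  lever1 <- lever0 %*% t(rot)  # hinge at the origin

  calib <- rbind(c(60, 0, 0), c(60, 0, 30))  # exactly 30 A apart

  build <- function(lever, id) {
    xyz <- rbind(motor, lever, calib)
    if (coord_noise_sd > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, coord_noise_sd),
                          ncol = 3)
    }
    resno <- c(seq_len(2L * n), 1L, 2L)
    chain <- c(rep("A", 2L * n), "X", "X")
    resid <- ifelse(resno %% 5L == 0L & chain == "A", "LYS", "ALA")
    as_xlms_model(data.frame(
      chain = chain, resno = resno, resid = resid, elety = "CA",
      elesy = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE), model_id = id, role = "primary")
  }
  model_a <- build(lever0, "hinge_ref")
  model_b <- build(lever1, "hinge_rot")

  # ground-truth distances between motor and lever lysines, recomputed
  # from the EMITTED coordinates (so stored truth matches the models
  # exactly, noise included)
  lys <- seq_len(2L * n)[seq_len(2L * n) %% 5L == 0L]
  lys_m <- lys[lys <= n]
  lys_l <- lys[lys > n]
  emitted_d <- function(model, i, j) ca_distance(model, "A", i, "A", j)
  pairs <- do.call(rbind, lapply(lys_m, function(i) {
    do.call(rbind, lapply(lys_l, function(j) {
      data.frame(resno_a = i, resno_b = j,
                 d_ref = emitted_d(model_a, i, j),
                 d_rot = emitted_d(model_b, i, j))
    }))
  }))
  truth <- list(angle_deg = angle_deg, hinge_axis = hinge_axis,
                pairs = pairs, lysines = lys,
                calibration_distance = ca_distance(model_a, "X", 1, "X", 2))

  if (!is.null(emit_dir)) {
    dir.create(emit_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in list(model_a, model_b)) {
      a <- m$atoms
      bio3d::write.pdb(
        file = file.path(emit_dir, paste0(m$model_id, ".pdb")),
        xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
        resno = a$resno, chain = a$chain, resid = a$resid,
        elety = a$elety)
    }
  }
  list(model_a = model_a, model_b = model_b, truth = truth,
       align_selection = paste0("A:1-", n),
       segment_selection = paste0("A:", n + 1L, "-", 2L * n))
}

#' End-to-end benchmark with planted dynamics categories
#'
#' Builds a paired quantification table and structure set in which every
#' dynamics category has at least one planted representative: cross-links
#' placed at controlled Calpha distances in two primary (open-conformation)
#' models and one alternate (bent-lever) model, with planted fold changes.
#' At `cv = 0` the full pipeline (normalize, aggregate, differential test,
#' distance annotation, classification) must recover the planted category
#' of every link exactly.
#'
#' @param cv Noise coefficient of variation (default 0).
#' @param n_replicates Replicates per condition (default 3).
#' @param seed Integer seed.
#' @return List: `peptides`, `sequences`, `models` (list of three
#'   `xlms_model`s with mappings set), `truth` (`data.frame`: `link`,
#'   `category`, `log2fc`), `conditions`.
#' @export
simulate_dynamics_benchmark <- function(cv = 0, n_replicates = 3, seed = 1) {
  set.seed(seed)
  sequences <- c(PRA = paste(rep("K", 40), collapse = ""))

  # planted links: residue pair, distances in (primary1, primary2,
  # alternate), planted log2 fold change, expected category
  plan <- data.frame(
    sa = c(1, 3, 5, 7, 9, 11, 13),
    sb = c(2, 4, 6, 8, 10, 12, 14),
    d1 = c(10, 40, 40, 40, 12, 10, NA),
    d2 = c(11, 41, 41, 41, 13, 11, NA),
    d_alt = c(10, 15, 40, 40, 12, 10, NA),
    log2fc = c(2, 2, 2, -2, -2, 0, 2),
    category = c("stabilized_state", "alternate_state_sampling",
                 "increased_dynamics", "lost_exploratory",
                 "redistribution", "no_change", "unannotated"),
    stringsAsFactors = FALSE)

  # place each pair in its own y-slab so distances are independent
  make_model <- function(dcol, id, role) {
    rows <- list()
    for (k in seq_len(nrow(plan))) {
      d <- plan[[dcol]][k]
      if (is.na(d)) next  # unannotated: residues absent from the model
      y <- 200 * k
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resno = c(plan$sa[k], plan$sb[k]), resid = "LYS",
        elety = "CA", elesy = "C",
        x = c(0, d), y = c(y, y), z = c(0, k),  # k: break collinearity
        stringsAsFactors = FALSE)
    }
    m <- as_xlms_model(do.call(rbind, rows), model_id = id, role = role)
    set_model_mapping(m, chain_map = c(PRA = "A"))
  }
  models <- list(make_model("d1", "S1_open", "primary"),
                 make_model("d2", "S1_open_alt", "primary"),
                 make_model("d_alt", "BH_bent", "alternate"))

  lf <- rep(c(1, 1.25, 0.8), length.out = n_replicates)
  lf <- c(lf, rev(lf))  # control then treated loadings
  conditions <- c("control", "treated")
  rows <- list()
  lfm <- matrix(lf, nrow = 2, byrow = TRUE)
  for (k in seq_len(nrow(plan))) {
    base <- 1e6 * (1 + k / 10)
    for (ci in 1:2) {
      mu <- base * if (ci == 2L) 2^plan$log2fc[k] else 1
      vals <- mu * lfm[ci, ] * lnoise(n_replicates, cv)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_a = "PRA", site_a = plan$sa[k],
        protein_b = "PRA", site_b = plan$sb[k],
        link_kind = "interpeptide",
        peptide = paste0("PEP", k), charge = 2L,
        condition = conditions[ci],
        replicate = paste0("R", seq_len(n_replicates)),
        intensity = vals, retention_time = NA_real_,
        candidate_sites = NA_character_, stringsAsFactors = FALSE)
    }
  }
  for (j in 1:40) {  # carriers
    base <- 5e6 * (1 + j / 20)
    for (ci in 1:2) {
      vals <- base * lfm[ci, ] * lnoise(n_replicates, cv)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_a = "PRA", site_a = NA_integer_,
        protein_b = NA_character_, site_b = NA_integer_,
        link_kind = "unreacted", peptide = paste0("CARRIER", j), charge = 2L,
        condition = conditions[ci],
        replicate = paste0("R", seq_len(n_replicates)),
        intensity = vals, retention_time = NA_real_,
        candidate_sites = NA_character_, stringsAsFactors = FALSE)
    }
  }
  peptides <- do.call(rbind, rows)
  rownames(peptides) <- NULL
  class(peptides) <- c("xlms_peptides", "data.frame")
  truth <- data.frame(
    link = link_key("PRA", plan$sa, "PRA", plan$sb),
    category = plan$category, log2fc = plan$log2fc,
    stringsAsFactors = FALSE)
  list(peptides = peptides, sequences = sequences, models = models,
       truth = truth, conditions = conditions)
}
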