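## Synthetic cohort generator.
##
## Emulates the inputs of a two-group structural MRI study: per-subject
## grey-matter partial-volume maps on a 2 mm grid, an integer atlas aligned
## to the same grid, and a covariate table (group, age, sex, education,
## total GM volume, physical/social anhedonia scales, illness duration,
## antipsychotic dose). The maps are latent-factor fields designed so that
## the small-worldness of the constructed similarity network is monotonically
## controlled by a per-subject "regularity" parameter, and so that anhedonia
## scores can be coupled to that latent regularity (inducing, not imposing,
## a sigma-scale correlation).

ICN_NAMES <- c("DMN", "CCN", "SVN", "DAN", "LN", "SMN", "VN")

#' Simulation configuration for a synthetic cohort
#'
#' Defaults emulate the study conditions of a schizophrenia / control
#' structural MRI cohort: 121 patients and 160 controls; physical anhedonia
#' scale (PAS, 0-61) means 21.5 +/- 9.6 vs 12.4 +/- 7.5; social anhedonia
#' scale (SAS, 0-40) means 16.4 +/- 6.9 vs 8.9 +/- 4.4, observed in only
#' 77/121 patients and 104/160 controls; total GM volume group ratio and
#' coefficients of variation matching 585.8 +/- 60.5 vs 600.0 +/- 59.3 cm^3
#' (rescaled to the synthetic brain size when `gm_volume_means_sds` is left
#' `NULL`). The regularity parameters control how lattice-like the latent
#' covariance of cube intensities is (higher regularity, higher expected
#' network sigma).
#'
#' @param n_patients,n_controls group sizes.
#' @param volume_shape integer length-3, voxels per axis (2 mm grid).
#' @param voxel_size_mm voxel size (isotropic, default 2).
#' @param regularity_patient,regularity_control group mean regularity in
#'   \[0, 1\].
#' @param regularity_sd between-subject SD of regularity (draws are clipped
#'   to \[0.02, 0.98\]).
#' @param gm_volume_means_sds list with `patient` and `control`, each
#'   `c(mean, sd)` in cm^3, or `NULL` to derive desk-scale defaults from
#'   `volume_shape` preserving the study's group ratio and CVs.
#' @param age_params,education_params,pas_params,sas_params lists with
#'   `patient` and `control` entries `c(mean, sd)`.
#' @param sex_female_fraction named numeric, probability of female per group.
#' @param rho_sigma_sas_patient,rho_sigma_sas_control target correlation
#'   between constructed network sigma and SAS, induced through the shared
#'   latent regularity.
#' @param sas_missing_fraction named numeric, fraction of each group with SAS
#'   absent.
#' @param duration_params,cpz_params `c(mean, sd)` for illness duration
#'   (years) and chlorpromazine-equivalent dose (mg), patients only.
#' @param n_regions number of synthetic atlas regions.
#' @param seed master seed.
#' @return object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(
    n_patients = 121L, n_controls = 160L,
    volume_shape = c(30L, 30L, 30L), voxel_size_mm = 2,
    regularity_patient = 0.62, regularity_control = 0.72,
    regularity_sd = 0.15,
    gm_volume_means_sds = NULL,
    age_params = list(patient = c(34.5, 8.8), control = c(33.4, 6.8)),
    education_params = list(patient = c(13.3, 2.2), control = c(16.2, 2.8)),
    sex_female_fraction = c(patient = 55 / 123, control = 73 / 160),
    pas_params = list(patient = c(21.5, 9.6), control = c(12.4, 7.5)),
    sas_params = list(patient = c(16.4, 6.9), control = c(8.9, 4.4)),
    rho_sigma_sas_patient = 0,
    rho_sigma_sas_control = 0.36,
    sas_missing_fraction = c(patient = 44 / 121, control = 56 / 160),
    duration_params = c(9.7, 7.5),
    cpz_params = c(419.8, 337.3),
    n_regions = 14L,
    seed = 1L) {
  n_patients <- stop_if_not_count(n_patients, "n_patients")
  n_controls <- stop_if_not_count(n_controls, "n_controls")
  volume_shape <- vapply(rep_len(volume_shape, 3L), stop_if_not_count,
                         integer(1), name = "volume_shape", lo = 12L)
  stop_if_not_scalar(regularity_patient, "regularity_patient", 0, 1)
  stop_if_not_scalar(regularity_control, "regularity_control", 0, 1)
  stop_if_not_scalar(regularity_sd, "regularity_sd", 0, 1)
  for (nm in c("patient", "control")) {
    stop_if_not_scalar(sas_missing_fraction[[nm]],
                       paste0("sas_missing_fraction$", nm), 0, 1)
    stop_if_not_scalar(sex_female_fraction[[nm]],
                       paste0("sex_female_fraction$", nm), 0, 1)
  }
  stop_if_not_scalar(rho_sigma_sas_patient, "rho_sigma_sas_patient", -1, 1)
  stop_if_not_scalar(rho_sigma_sas_control, "rho_sigma_sas_control", -1, 1)
  n_regions <- stop_if_not_count(n_regions, "n_regions", lo = 2L)
  if (is.null(gm_volume_means_sds)) {
    # derive desk-scale GM volume targets: control mean = 62% mean intensity
    # over the synthetic GM compartment; patient/control ratio and CVs match
    # the study's printed 585.8/600.0 and 60.5/585.8, 59.3/600.0
    n_vox <- 27L * length(brain_cube_ids(volume_shape))
    ctrl_mean <- 0.62 * n_vox * 0.008
    pat_mean <- ctrl_mean * 585.8 / 600.0
    gm_volume_means_sds <- list(patient = c(pat_mean, pat_mean * 60.5 / 585.8),
                                control = c(ctrl_mean, ctrl_mean * 59.3 / 600.0))
  }
  cfg <- list(n_patients = n_patients, n_controls = n_controls,
              volume_shape = volume_shape, voxel_size_mm = voxel_size_mm,
              regularity_patient = regularity_patient,
              regularity_control = regularity_control,
              regularity_sd = regularity_sd,
              gm_volume_means_sds = gm_volume_means_sds,
              age_params = age_params, education_params = education_params,
              sex_female_fraction = sex_female_fraction,
              pas_params = pas_params, sas_params = sas_params,
              rho_sigma_sas_patient = rho_sigma_sas_patient,
              rho_sigma_sas_control = rho_sigma_sas_control,
              sas_missing_fraction = sas_missing_fraction,
              duration_params = duration_params, cpz_params = cpz_params,
              n_regions = n_regions, seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

# brain mask ------------------------------------------------------------

# ball mask of GM cube centers: returns linear cube ids (on the 3-voxel
# tiling lattice) whose center lies within the largest centered ball that
# leaves a 1-cube margin
brain_cube_ids <- function(volume_shape) {
  nb <- volume_shape %/% 3L
  ctr <- (nb + 1) / 2
  r <- min(nb) / 2 - 0.5
  cx <- rep(seq_len(nb[1]), times = nb[2] * nb[3])
  cy <- rep(rep(seq_len(nb[2]), each = nb[1]), times = nb[3])
  cz <- rep(seq_len(nb[3]), each = nb[1] * nb[2])
  which(((cx - ctr[1])^2 + (cy - ctr[2])^2 + (cz - ctr[3])^2) <= r^2)
}

# voxel-level logical mask corresponding to brain_cube_ids
brain_voxel_mask <- function(volume_shape) {
  nb <- volume_shape %/% 3L
  cube <- array(FALSE, nb)
  cube[brain_cube_ids(volume_shape)] <- TRUE
  vox <- array(FALSE, volume_shape)
  big <- cube[rep(seq_len(nb[1]), each = 3L),
              rep(seq_len(nb[2]), each = 3L),
              rep(seq_len(nb[3]), each = 3L), drop = FALSE]
  vox[seq_len(3L * nb[1]), seq_len(3L * nb[2]), seq_len(3L * nb[3])] <- big
  vox
}

# atlas -----------------------------------------------------------------

#' Generate a synthetic atlas parcellation on the subject grid
#'
#' Partitions the foreground into `n_regions` contiguous regions by
#' multi-source breadth-first region growing from randomly placed seed
#' voxels (6-connectivity; ties claimed by the smallest region id). Each
#' region is mapped to one of the 7 intrinsic connectivity networks (ICNs)
#' cyclically, so every ICN receives at least one region whenever
#' `n_regions >= 7`.
#'
#' @param volume_shape integer length-3 grid size.
#' @param n_regions number of regions (>= 2).
#' @param seed integer seed.
#' @param mask logical array of foreground voxels, or `NULL` for the
#'   package's synthetic brain mask on that grid.
#' @return object of class `gm_atlas`: `labels` (integer 3D array, 0 =
#'   background) and `region_table` (region_id, name, grouping).
#' @export
generate_atlas_labels <- function(volume_shape, n_regions, seed = 1L,
                                  mask = NULL) {
  volume_shape <- vapply(rep_len(volume_shape, 3L), stop_if_not_count,
                         integer(1), name = "volume_shape", lo = 3L)
  n_regions <- stop_if_not_count(n_regions, "n_regions", lo = 2L)
  if (is.null(mask)) mask <- brain_voxel_mask(volume_shape)
  stopifnot(is.logical(mask), all(dim(mask) == volume_shape))
  fg <- which(mask)
  if (n_regions > length(fg))
    stop("`n_regions` exceeds the number of foreground voxels", call. = FALSE)
  d <- volume_shape
  labels <- integer(prod(d))
  seeds <- with_seed(seed, sample(fg, n_regions))
  labels[seeds] <- seq_len(n_regions)
  frontier <- split(seeds, seq_len(n_regions))
  nbr_off <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                  c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  in_mask <- logical(prod(d)); in_mask[fg] <- TRUE
  repeat {
    grew <- FALSE
    for (r in seq_len(n_regions)) {
      f <- frontier[[r]]
      if (!length(f)) next
      co <- arrayInd(f, d)
      new_idx <- integer(0)
      for (off in nbr_off) {
        nb <- co + matrix(off, nrow(co), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        li <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
        li <- li[in_mask[li] & labels[li] == 0L]
        if (length(li)) {
          labels[li] <- r
          new_idx <- c(new_idx, li)
        }
      }
      frontier[[r]] <- unique(new_idx)
      if (length(new_idx)) grew <- TRUE
    }
    if (!grew) break
  }
  # mask components unreachable from any seed (possible for disconnected
  # masks): assign to the nearest seed by Euclidean distance
  left <- fg[labels[fg] == 0L]
  if (length(left)) {
    co <- arrayInd(left, d)
    sc <- arrayInd(seeds, d)
    dist2 <- outer(rowSums(co^2), rowSums(sc^2), "+") - 2 * co %*% t(sc)
    labels[left] <- max.col(-dist2, ties.method = "first")
  }
  tab <- data.frame(region_id = seq_len(n_regions),
                    name = sprintf("region_%02d", seq_len(n_regions)),
                    grouping = ICN_NAMES[(seq_len(n_regions) - 1L) %% 7L + 1L],
                    stringsAsFactors = FALSE)
  structure(list(labels = array(labels, d), region_table = tab),
            class = "gm_atlas")
}

#' @export
print.gm_atlas <- function(x, ...) {
  cat(sprintf("<gm_atlas> %d regions over %d foreground voxels (%s grid)\n",
              nrow(x$region_table), sum(x$labels > 0),
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

# GM volume -------------------------------------------------------------

# order brain cubes: by region (majority label of the cube's voxels) when an
# atlas is supplied, raster order within region; raster order otherwise
order_brain_cubes <- function(volume_shape, cube_ids, atlas = NULL) {
  if (is.null(atlas)) return(list(order = seq_along(cube_ids),
                                  region = rep(NA_integer_, length(cube_ids))))
  nb <- volume_shape %/% 3L
  ori <- (arrayInd(cube_ids, nb) - 1L) * 3L    # 0-based voxel origins
  L <- vapply(1:27, function(k) {
    dd <- arrayInd(k, c(3L, 3L, 3L)) - 1L
    atlas$labels[cbind(ori[, 1] + dd[1] + 1L, ori[, 2] + dd[2] + 1L,
                       ori[, 3] + dd[3] + 1L)]
  }, integer(length(cube_ids)))
  reg <- majority_region(matrix(L, nrow = length(cube_ids)),
                         max(atlas$region_table$region_id))
  list(order = order(reg, seq_along(cube_ids), na.last = TRUE), region = reg)
}

#' Generate one synthetic GM partial-volume map
#'
#' Produces a contiguous ball-shaped GM compartment built from
#' non-overlapping 3x3x3 cubes. Each cube's 27 intensities are a mixture of
#' (i) a ring-banded latent factor field over the ordered cube sequence
#' (overlapping windows of shared factors, giving a lattice-like similarity
#' topology) and (ii) a single global factor with heterogeneous per-cube
#' loadings (giving an unstructured, densely shared topology). The subject's
#' `regularity` sets the mixture: regularity 1 is a pure ring-banded field
#' (high expected network sigma), regularity 0 is dominated by the global
#' factor (sigma near 1). Intensities are affinely mapped into \[0, 1\] so
#' the realized total GM volume matches `gm_target` within 5%.
#'
#' @param config a [simulation_config()] (supplies `volume_shape`; its
#'   control-group GM mean is the default volume target).
#' @param subject_regularity scalar in \[0, 1\].
#' @param seed integer seed.
#' @param gm_target target total GM volume in cm^3 (default: the config's
#'   control-group mean).
#' @param atlas optional `gm_atlas` used to order cubes by region, aligning
#'   the latent ring with atlas regions; when supplied,
#'   `region_regularity` can override regularity per region id.
#' @param region_regularity optional named numeric vector (names = region
#'   ids) of per-region regularity overrides.
#' @param subject_id identifier stored on the volume.
#' @return a [gm_volume()] on the 2 mm grid.
#' @export
generate_gm_volume <- function(config, subject_regularity, seed = 1L,
                               gm_target = NULL, atlas = NULL,
                               region_regularity = NULL,
                               subject_id = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  stop_if_not_scalar(subject_regularity, "subject_regularity", 0, 1)
  shape <- config$volume_shape
  cube_ids <- brain_cube_ids(shape)
  m <- length(cube_ids)
  if (m < 30L)
    stop("volume_shape too small: fewer than 30 cubes fit in the GM mask",
         call. = FALSE)
  if (is.null(gm_target)) gm_target <- config$gm_volume_means_sds$control[1]
  ord <- order_brain_cubes(shape, cube_ids, atlas)
  tau <- 0.1                               # voxel noise variance fraction
  V <- with_seed(seed, {
    # per-cube regularity (region overrides apply through the atlas)
    reg <- rep(subject_regularity, m)
    if (!is.null(region_regularity)) {
      if (is.null(atlas))
        stop("`region_regularity` requires an `atlas`", call. = FALSE)
      cube_region <- ord$region
      hit <- match(as.character(cube_region), names(region_regularity))
      reg[!is.na(hit)] <- region_regularity[hit[!is.na(hit)]]
    }
    # latent window width per cube: regularity 1 -> narrow overlapping
    # windows along the ring (sparse band lattice, high sigma); regularity 0
    # -> windows spanning the whole ring (all cubes share one factor set,
    # complete graph, sigma = 1)
    wdt <- pmin(m, pmax(4L, as.integer(round(
      m * (0.06 + 0.94 * (1 - reg)^1.5)))))
    pos <- integer(m); pos[ord$order] <- seq_len(m)  # rank along the ring
    H <- matrix(stats::rnorm(m * 27L), m, 27L)
    C <- apply(rbind(H, H), 2, cumsum)
    C <- rbind(0, C)                       # C[k+1, ] = sum of first k rows
    f <- (C[pos + wdt, , drop = FALSE] - C[pos, , drop = FALSE]) / sqrt(wdt)
    eps <- matrix(stats::rnorm(m * 27L), m, 27L)
    sqrt(1 - tau) * f + sqrt(tau) * eps
  })
  # affine map into [0,1] hitting the GM volume target (bisection on the
  # offset; the multiplicative scale is fixed so correlations are preserved)
  s <- 0.11
  n_vox <- 27 * m
  target_sum <- gm_target / (prod(rep(config$voxel_size_mm, 3)) / 1000)
  if (target_sum < 0.05 * n_vox || target_sum > 0.95 * n_vox)
    stop(sprintf(
      "gm_target %.1f cm^3 is not attainable inside a %d-cube GM mask",
      gm_target, m), call. = FALSE)
  f_sum <- function(mu) sum(pmin(pmax(mu + s * V, 0), 1))
  lo <- 0; hi <- 1
  for (it in 1:28) {
    mid <- (lo + hi) / 2
    if (f_sum(mid) < target_sum) lo <- mid else hi <- mid
  }
  X <- pmin(pmax((lo + hi) / 2 + s * V, 0), 1)
  # assemble the voxel array
  arr <- array(0, shape)
  nb <- shape %/% 3L
  co <- (arrayInd(cube_ids, nb) - 1L) * 3L
  for (i in seq_len(m))
    arr[co[i, 1] + 1:3, co[i, 2] + 1:3, co[i, 3] + 1:3] <- X[i, ]
  gm_volume(arr, voxel_size = rep(config$voxel_size_mm, 3),
            subject_id = subject_id)
}

# toy graphs ------------------------------------------------------------

#' Generate a toy graph fixture
#'
#' Standard undirected simple graphs used to validate the graph-metric
#' layer: ring lattices, Erdos-Renyi G(n, p), Watts-Strogatz small worlds,
#' complete graphs, stars and paths. Deterministic given `seed`.
#'
#' @param kind one of `"ring_lattice"`, `"erdos_renyi"`, `"watts_strogatz"`,
#'   `"complete"`, `"star"`, `"path"`.
#' @param n vertex count (>= 3).
#' @param param `ring_lattice`: neighbors per side; `erdos_renyi`: edge
#'   probability; `watts_strogatz`: `c(neighbors_per_side,
#'   rewiring_probability)`; ignored for the deterministic kinds.
#' @param seed integer seed.
#' @return an undirected simple [igraph::graph].
#' @export
generate_toy_graph <- function(kind, n, param = NULL, seed = 1L) {
  n <- stop_if_not_count(n, "n", lo = 3L)
  kind <- match.arg(kind, c("ring_lattice", "erdos_renyi", "watts_strogatz",
                            "complete", "star", "path"))
  g <- switch(kind,
    ring_lattice = {
      k <- stop_if_not_count(param[1], "param (neighbors per side)")
      if (2 * k >= n) stop("ring lattice needs 2*param < n", call. = FALSE)
      if (k == 1L) igraph::make_ring(n) else
        igraph::connect(igraph::make_ring(n), k)
    },
    erdos_renyi = {
      stop_if_not_scalar(param[1], "param (edge probability)", 0, 1)
      with_seed(seed, igraph::sample_gnp(n, param[1]))
    },
    watts_strogatz = {
      if (length(param) != 2L)
        stop("watts_strogatz needs param = c(neighbors_per_side, rewiring_prob)",
             call. = FALSE)
      k <- stop_if_not_count(param[1], "param[1] (neighbors per side)")
      stop_if_not_scalar(param[2], "param[2] (rewiring probability)", 0, 1)
      with_seed(seed, igraph::sample_smallworld(1, n, k, param[2]))
    },
    complete = igraph::make_full_graph(n),
    star = igraph::make_star(n, mode = "undirected"),
    path = igraph::make_ring(n, circular = FALSE))
  igraph::simplify(g)
}

# cohort ----------------------------------------------------------------

rnorm_clipped <- function(n, mean, sd, lo, hi)
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Generate a full synthetic cohort
#'
#' Draws per-subject covariates as configured, generates one GM volume per
#' subject (regularity drawn around the group mean), and one shared atlas on
#' the common grid. SAS scores are generated as a linear function of the
#' subject's latent regularity plus noise, with the within-group
#' regularity-SAS correlation set to the configured target; because network
#' sigma is driven by the same latent regularity, the realized sigma-SAS
#' correlation approaches the target as the cohort grows (induced, not
#' imposed). The configured fraction of each group has SAS set missing.
#'
#' @param config a [simulation_config()].
#' @param volumes generate the GM volumes (set `FALSE` to draw only the
#'   covariate table, e.g. for statistics-layer simulations).
#' @return object of class `gm_cohort`: `covariates` (data frame),
#'   `volumes` (named list of [gm_volume()] or `NULL`), `atlas`, `config`.
#' @export
generate_cohort <- function(config, volumes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  atlas <- generate_atlas_labels(config$volume_shape, config$n_regions,
                                 seed = derive_seed(config$seed, "atlas"))
  groups <- c(rep("patient", config$n_patients),
              rep("control", config$n_controls))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  cov <- with_seed(derive_seed(config$seed, "covariates"), {
    out <- data.frame(subject_id = ids, group = groups,
                      stringsAsFactors = FALSE)
    out$age <- NA_real_; out$sex <- NA_character_; out$education <- NA_real_
    out$pas <- NA_real_; out$sas <- NA_real_; out$regularity <- NA_real_
    out$gm_target <- NA_real_
    out$duration_illness <- NA_real_; out$cpz_dose <- NA_real_
    for (grp in c("patient", "control")) {
      sel <- which(groups == grp)
      ng <- length(sel)
      ap <- config$age_params[[grp]]; ep <- config$education_params[[grp]]
      pp <- config$pas_params[[grp]]; sp <- config$sas_params[[grp]]
      gp <- config$gm_volume_means_sds[[grp]]
      mu_reg <- if (grp == "patient") config$regularity_patient else
        config$regularity_control
      rho <- if (grp == "patient") config$rho_sigma_sas_patient else
        config$rho_sigma_sas_control
      out$age[sel] <- rnorm_clipped(ng, ap[1], ap[2], 18, 80)
      out$sex[sel] <- ifelse(
        stats::runif(ng) < config$sex_female_fraction[[grp]],
        "female", "male")
      out$education[sel] <- rnorm_clipped(ng, ep[1], ep[2], 6, 25)
      out$pas[sel] <- round(rnorm_clipped(ng, pp[1], pp[2], 0, 61))
      # regularity draws stay inside the generator's stable regime: above
      # ~0.9 the latent band graph fragments and sigma becomes erratic
      reg <- rnorm_clipped(ng, mu_reg, config$regularity_sd, 0.05, 0.88)
      out$regularity[sel] <- reg
      # SAS couples to the sigma link of regularity (expected sigma grows
      # log-linearly with regularity over the operating range), so the
      # induced Pearson correlation with constructed sigma approaches the
      # configured target; coupling to the latent trait, never to realized
      # sigma, avoids circularity
      link <- exp(2.4 * reg)
      z_reg <- if (ng > 1 && stats::sd(link) > 0)
        (link - mean(link)) / stats::sd(link) else rep(0, ng)
      sas_lat <- rho * z_reg + sqrt(max(0, 1 - rho^2)) * stats::rnorm(ng)
      out$sas[sel] <- round(pmin(pmax(sp[1] + sp[2] * sas_lat, 0), 40))
      n_miss <- round(config$sas_missing_fraction[[grp]] * ng)
      if (n_miss > 0) out$sas[sel[sample.int(ng, n_miss)]] <- NA_real_
      out$gm_target[sel] <- rnorm_clipped(ng, gp[1], gp[2],
                                          gp[1] - 3 * gp[2], gp[1] + 3 * gp[2])
      if (grp == "patient") {
        out$duration_illness[sel] <-
          rnorm_clipped(ng, config$duration_params[1], config$duration_params[2],
                        0.5, 50)
        out$cpz_dose[sel] <-
          rnorm_clipped(ng, config$cpz_params[1], config$cpz_params[2], 0, 2500)
      }
    }
    out
  })
  vols <- NULL
  if (volumes) {
    vols <- lapply(seq_len(n), function(i) {
      generate_gm_volume(config, cov$regularity[i],
                         seed = derive_seed(config$seed, "vol", ids[i]),
                         gm_target = cov$gm_target[i], atlas = atlas,
                         subject_id = ids[i])
    })
    names(vols) <- ids
    cov$gm_volume <- vapply(vols, total_gm_volume, numeric(1))
  } else {
    cov$gm_volume <- cov$gm_target
  }
  structure(list(covariates = cov, volumes = vols, atlas = atlas,
                 config = config),
            class = "gm_cohort")
}

#' @export
print.gm_cohort <- function(x, ...) {
  cat(sprintf("<gm_cohort> %d patients + %d controls, %s grid, %d atlas regions%s\n",
              sum(x$covariates$group == "patient"),
              sum(x$covariates$group == "control"),
              paste(x$config$volume_shape, collapse = "x"),
              nrow(x$atlas$region_table),
              if (is.null(x$volumes)) " (covariates only)" else ""))
  invisible(x)
}
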