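#' Configuration for the synthetic fracture-callus generator
#'
#' The generator lays spots on a hexagonal lattice, draws a fracture plane,
#' and gives every gene a mean surface over SpatialTime `s` (the min-max
#' normalized distance to the plane):
#' noise genes are flat; marker genes carry a `1 + amplitude` uplift inside
#' their tissue domain; gradient-class and module genes follow a Gaussian
#' bump `1 + amplitude * exp(-(s - peak)^2 / (2 * sigma^2))`. Counts are
#' negative binomial with spot-level size factors. In the `mutant` genotype
#' each module's bump amplitude is multiplied by its `genotype_multiplier`
#' (0 removes the pathway gradient, >1 amplifies it).
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param spot_pitch center-to-center spacing in pixel units.
#' @param plane_points polyline for the fracture plane; default is a
#'   vertical line at the left edge of the lattice.
#' @param domain_spec named list of `c(lo, hi)` SpatialTime bands, ordered,
#'   covering `[0, 1]`.
#' @param n_marker_genes_per_domain marker genes per domain.
#' @param n_gradient_genes_per_class gradient genes per dynamic class.
#' @param class_peaks bump peak positions, strictly increasing in `[0, 1]`.
#' @param class_width bump standard deviation in SpatialTime units.
#' @param amplitude bump / uplift fold effect.
#' @param n_noise_genes flat genes.
#' @param module_spec named list of `list(n, peak, genotype_multiplier)`.
#' @param baseline_mean expected count per gene per spot at size factor 1.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param libsize_cv coefficient of variation of spot size factors.
#' @param seed top-level seed; sub-streams use fixed offsets.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_rows = 40, n_cols = 50, spot_pitch = 100,
                             plane_points = NULL,
                             domain_spec = list(progenitor = c(0, 0.25),
                                                cartilage = c(0.25, 0.5),
                                                woven_bone = c(0.5, 0.75),
                                                cortical = c(0.75, 1)),
                             n_marker_genes_per_domain = 25,
                             n_gradient_genes_per_class = 50,
                             class_peaks = c(0.05, 0.30, 0.60, 0.95),
                             class_width = 0.12, amplitude = 2,
                             n_noise_genes = 2000,
                             module_spec = list(
                               BMP = list(n = 30, peak = 0.30, genotype_multiplier = 0),
                               WNT = list(n = 30, peak = 0.45, genotype_multiplier = 0),
                               MAPK = list(n = 30, peak = 0.15, genotype_multiplier = 2)),
                             baseline_mean = 5, dispersion = 0.5,
                             libsize_cv = 0.2, seed = 1) {
  if (is.null(plane_points)) {
    height <- (n_rows - 1) * spot_pitch * sqrt(3) / 2
    plane_points <- rbind(c(0, 0), c(0, max(height, spot_pitch)))
  }
  cfg <- list(n_rows = n_rows, n_cols = n_cols, spot_pitch = spot_pitch,
              plane_points = as.matrix(plane_points), domain_spec = domain_spec,
              n_marker_genes_per_domain = n_marker_genes_per_domain,
              n_gradient_genes_per_class = n_gradient_genes_per_class,
              class_peaks = class_peaks, class_width = class_width,
              amplitude = amplitude, n_noise_genes = n_noise_genes,
              module_spec = module_spec, baseline_mean = baseline_mean,
              dispersion = dispersion, libsize_cv = libsize_cv, seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_rows >= 2, n_cols >= 2, spot_pitch > 0,
              baseline_mean > 0, dispersion > 0, libsize_cv >= 0,
              amplitude >= 0, class_width > 0,
              n_marker_genes_per_domain >= 0,
              n_gradient_genes_per_class >= 0, n_noise_genes >= 0)
    if (any(class_peaks < 0) || any(class_peaks > 1) ||
        any(diff(class_peaks) <= 0))
      stop("class_peaks must be strictly increasing within [0, 1]", call. = FALSE)
    if (is.null(names(domain_spec)) || anyDuplicated(names(domain_spec)))
      stop("domain_spec must be a uniquely named list", call. = FALSE)
  })
  invisible(cfg)
}

# gene catalog implied by a config: name, role, class, module, domain, peak
gene_catalog <- function(cfg) {
  rows <- list()
  for (d in names(cfg$domain_spec)) {
    n <- cfg$n_marker_genes_per_domain
    if (n > 0)
      rows[[length(rows) + 1]] <- data.frame(
        gene = sprintf("mk_%s_%03d", d, seq_len(n)), role = "marker",
        class = "none", module = "none", domain = d, peak = NA_real_)
  }
  cls <- class_names(length(cfg$class_peaks))
  for (i in seq_along(cfg$class_peaks)) {
    n <- cfg$n_gradient_genes_per_class
    if (n > 0)
      rows[[length(rows) + 1]] <- data.frame(
        gene = sprintf("gr_%s_%03d", cls[i], seq_len(n)), role = "gradient",
        class = cls[i], module = "none", domain = "none",
        peak = cfg$class_peaks[i])
  }
  for (m in names(cfg$module_spec)) {
    sp <- cfg$module_spec[[m]]
    if (sp$n > 0)
      rows[[length(rows) + 1]] <- data.frame(
        gene = sprintf("md_%s_%03d", m, seq_len(sp$n)), role = "module",
        class = "none", module = m, domain = "none", peak = sp$peak)
  }
  if (cfg$n_noise_genes > 0)
    rows[[length(rows) + 1]] <- data.frame(
      gene = sprintf("ns_%04d", seq_len(cfg$n_noise_genes)), role = "noise",
      class = "none", module = "none", domain = "none", peak = NA_real_)
  cat <- do.call(rbind, rows)
  if (anyDuplicated(cat$gene)) stop("gene names not unique", call. = FALSE)
  cat
}

# hexagonal lattice coordinates (odd rows offset by half a pitch)
hex_lattice <- function(n_rows, n_cols, pitch) {
  g <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  x <- g$col * pitch + (g$row %% 2) * pitch / 2
  y <- g$row * pitch * sqrt(3) / 2
  list(coords = cbind(x = x, y = y), array_pos = cbind(g$row, g$col))
}

#' Generate one synthetic fracture-callus section with ground truth
#'
#' @param config a [synthetic_config()].
#' @param genotype `"control"` or `"mutant"`.
#' @param seed_offset added to `config$seed` to derive this section's RNG
#'   stream (used by [generate_pair()]).
#' @return list with `section` (a [spatial_section()]) and `truth`
#'   (`synthetic_truth`: `domain_of_spot`, `true_spatialtime`,
#'   `class_of_gene`, `module_of_gene`, `genotype`, `config`, plus the full
#'   gene catalog).
#' @export
generate_section <- function(config, genotype = c("control", "mutant"),
                             seed_offset = 0L) {
  genotype <- match.arg(genotype)
  validate_synthetic_config(config)
  lat <- hex_lattice(config$n_rows, config$n_cols, config$spot_pitch)
  plane <- fracture_plane(config$plane_points)
  d <- polyline_distance(lat$coords, plane)
  s <- if (diff(range(d)) == 0) rep(0, length(d)) else (d - min(d)) / (max(d) - min(d))
  # domain by SpatialTime band (first band owning s, last band closed above)
  domains <- names(config$domain_spec)
  dom <- rep(NA_character_, length(s))
  for (i in seq_along(domains)) {
    band <- config$domain_spec[[i]]
    hit <- s >= band[1] & (s < band[2] | (i == length(domains) & s <= band[2]))
    dom[is.na(dom) & hit] <- domains[i]
  }
  empty <- setdiff(domains, unique(dom))
  if (length(empty))
    stop("lattice too small: no spots fall in domain band '", empty[1], "'",
         call. = FALSE)
  cat <- gene_catalog(config)
  n_spot <- nrow(lat$coords); n_gene <- nrow(cat)
  # per-gene fold surface over spots
  fold <- matrix(1, n_spot, n_gene)
  for (j in seq_len(n_gene)) {
    amp <- config$amplitude
    if (cat$role[j] == "marker") {
      fold[, j] <- 1 + amp * (dom == cat$domain[j])
    } else if (cat$role[j] %in% c("gradient", "module")) {
      if (cat$role[j] == "module" && genotype == "mutant")
        amp <- amp * config$module_spec[[cat$module[j]]]$genotype_multiplier
      fold[, j] <- 1 + amp * exp(-(s - cat$peak[j])^2 / (2 * config$class_width^2))
    }
  }
  counts <- withr_seed(config$seed + seed_offset, {
    sf <- if (config$libsize_cv > 0) {
      # lognormal size factors with unit mean and the requested CV
      sdl <- sqrt(log(1 + config$libsize_cv^2))
      exp(stats::rnorm(n_spot, -sdl^2 / 2, sdl))
    } else rep(1, n_spot)
    mu <- config$baseline_mean * sf * fold
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           n_spot, n_gene)
  })
  barcodes <- sprintf("spot_%05d", seq_len(n_spot))
  section <- spatial_section(
    counts = counts, coords = lat$coords, spot_ids = barcodes,
    gene_ids = cat$gene, array_pos = lat$array_pos,
    metadata = data.frame(in_tissue = TRUE, domain = dom, genotype = genotype),
    section_id = paste0("synthetic_", genotype))
  truth <- structure(list(
    domain_of_spot = stats::setNames(dom, barcodes),
    true_spatialtime = stats::setNames(s, barcodes),
    class_of_gene = stats::setNames(cat$class, cat$gene),
    module_of_gene = stats::setNames(cat$module, cat$gene),
    gene_catalog = cat, genotype = genotype, plane = plane,
    config = config), class = "synthetic_truth")
  list(section = section, truth = truth)
}

#' Generate a matched control/mutant section pair
#'
#' The two sections share the gene universe, lattice and fracture plane and
#' differ only in the genotype multipliers applied to module genes and in
#' the noise realization (distinct derived seeds).
#'
#' @param config a [synthetic_config()].
#' @return list with elements `control` and `mutant`, each as returned by
#'   [generate_section()].
#' @export
generate_pair <- function(config) {
  list(control = generate_section(config, "control", seed_offset = 0L),
       mutant = generate_section(config, "mutant", seed_offset = 10000L))
}

#' Generate a cross-species section pair with a known ortholog table
#'
#' Section B is generated from the same configuration under renamed gene
#' symbols linked one-to-one to section A's by an ortholog table. A fraction
#' `scramble` of B's genes have their spatial expression profiles randomly
#' permuted among themselves, destroying the cross-species correspondence
#' for those genes; at `scramble = 1` the gene-to-profile assignment in B is
#' a uniform random permutation of A's, i.e. exactly the gene-label
#' permutation null of [cluster_correspondence()].
#'
#' @param config a [synthetic_config()].
#' @param scramble fraction of genes whose profile is permuted in B.
#' @return list with `a`, `b` (each `list(section, truth)`), and
#'   `orthologs` (a data.frame usable with [ortholog_map()]).
#' @export
generate_ortholog_pair <- function(config, scramble = 0) {
  stopifnot(scramble >= 0, scramble <= 1)
  a <- generate_section(config, "control", seed_offset = 0L)
  cat <- gene_catalog(config)
  n_scr <- floor(scramble * nrow(cat))
  cat_b <- cat
  scr <- integer(0)
  if (n_scr > 0) {
    # a random permutation of spatial profiles among the scrambled genes,
    # drawn from the full gene universe (noise included): at scramble = 1
    # the gene-to-profile map of B is a uniform permutation of A's, i.e.
    # exactly the gene-label permutation null of cluster_correspondence
    scr <- withr_seed(config$seed + 77L, sample(nrow(cat), n_scr))
    perm <- withr_seed(config$seed + 78L, sample(scr))
    prof <- c("role", "class", "module", "domain", "peak")
    cat_b[scr, prof] <- cat[perm, prof]
  }
  b <- generate_section_with_catalog(config, cat_b, seed_offset = 20000L)
  b$section$gene_ids <- paste0(cat$gene, "_b")
  colnames(b$section$counts) <- b$section$gene_ids
  names(b$truth$class_of_gene) <- b$section$gene_ids
  names(b$truth$module_of_gene) <- b$section$gene_ids
  b$section$section_id <- "synthetic_speciesB"
  orthologs <- data.frame(symbol_a = cat$gene, symbol_b = paste0(cat$gene, "_b"),
                          stringsAsFactors = FALSE)
  list(a = a, b = b, orthologs = orthologs, scrambled = cat$gene[scr])
}

# internal: generate_section but with an externally modified gene catalog
generate_section_with_catalog <- function(config, cat, seed_offset) {
  base <- config
  out <- generate_section(base, "control", seed_offset = seed_offset)
  lat <- hex_lattice(config$n_rows, config$n_cols, config$spot_pitch)
  plane <- fracture_plane(config$plane_points)
  d <- polyline_distance(lat$coords, plane)
  s <- (d - min(d)) / (max(d) - min(d))
  dom <- out$truth$domain_of_spot
  n_spot <- nrow(lat$coords); n_gene <- nrow(cat)
  fold <- matrix(1, n_spot, n_gene)
  for (j in seq_len(n_gene)) {
    if (cat$role[j] == "marker") {
      fold[, j] <- 1 + config$amplitude * (dom == cat$domain[j])
    } else if (cat$role[j] %in% c("gradient", "module")) {
      fold[, j] <- 1 + config$amplitude *
        exp(-(s - cat$peak[j])^2 / (2 * config$class_width^2))
    }
  }
  counts <- withr_seed(config$seed + seed_offset, {
    sf <- if (config$libsize_cv > 0) {
      sdl <- sqrt(log(1 + config$libsize_cv^2))
      exp(stats::rnorm(n_spot, -sdl^2 / 2, sdl))
    } else rep(1, n_spot)
    mu <- config$baseline_mean * sf * fold
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           n_spot, n_gene)
  })
  out$section$counts <- as_sparse_counts(
    `dimnames<-`(counts, dimnames(out$section$counts)))
  out$truth$gene_catalog <- cat
  out
}

#' Write a synthetic section, its truth tables and config to disk
#'
#' Emits the 10x-style layout read by [read_spatial_dataset()] plus
#' `truth_spots.tsv`, `truth_genes.tsv` and `config.json`.
#'
#' @param sim output of [generate_section()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(sim, path) {
  write_spatial_dataset(sim$section, path)
  utils::write.table(
    data.frame(barcode = names(sim$truth$domain_of_spot),
               domain = sim$truth$domain_of_spot,
               true_spatialtime = sim$truth$true_spatialtime),
    file.path(path, "truth_spots.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$truth$gene_catalog, file.path(path, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(x = sim$truth$plane$points[, 1],
                              y = sim$truth$plane$points[, 2]),
                   file.path(path, "plane.csv"), row.names = FALSE, quote = FALSE)
  cfg <- unclass(sim$truth$config)
  cfg$plane_points <- lapply(seq_len(nrow(cfg$plane_points)), function(i)
    as.numeric(cfg$plane_points[i, ]))
  jsonlite::write_json(cfg, file.path(path, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
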