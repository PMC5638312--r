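#' Read a flat key/value run configuration
#'
#' One `key: value` pair per line; `#` starts a comment; comma-separated
#' values become vectors; numeric-looking values are converted.
#'
#' @param path config file.
#' @return named list; attribute `"hash"` carries a config fingerprint that
#'   is stamped into every output file.
#' @export
read_run_config <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))
  if (any(lengths(kv) != 3)) stop("malformed config line: ",
                                  ln[lengths(kv) != 3][1])
  cfg <- lapply(kv, function(m) {
    v <- strsplit(m[3], ",\\s*")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(cfg) <- vapply(kv, function(m) trimws(m[2]), "")
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

# FNV-1a over the deparsed config; no external digest dependency
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    # 32-bit FNV-1a in doubles: xor low byte, multiply mod 2^32
    h <- (bitwXor(h %% 2^31 + (h >= 2^31) * 0, b) + (h >= 2^31) * 2^31)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stamp <- function(path, hash) {
  txt <- readLines(path)
  writeLines(c(paste0("# config_hash: ", hash), txt), path)
}

cfg_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run the genetics track end to end
#'
#' Reads genotypes, then writes the locus table, group table (Ar/PAr at g),
#' Nei decomposition, AMOVA, pairwise F_ST, chi-square table, NJ tree with
#' locus-bootstrap supports, PCA scores, per-K Q matrices with the Evanno
#' table and, when accession coordinates are present, IDW rasters of Ar,
#' PAr and He. Any stage failure aborts with a stage-named error; files
#' written before the failure are kept.
#'
#' @param cfg list from [read_run_config()] (keys: `genotypes`, `out_dir`,
#'   optional `g`, `n_perm`, `K_min`, `K_max`, `reps`, `burnin`, `sweeps`,
#'   `boot_reps`, `seed`, `idw_cells`).
#' @return invisible named vector of output paths.
#' @export
run_genetics <- function(cfg) {
  hash <- attr(cfg, "hash") %||% config_hash(cfg)
  out <- cfg_get(cfg, "out_dir", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg_get(cfg, "seed", 1)
  paths <- c()
  emit <- function(df, name) {
    p <- file.path(out, name)
    write_tsv_table(df, p); stamp(p, hash)
    paths[name] <<- p
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))

  gt <- stage("read", read_genotype_table(cfg$genotypes))
  ac <- allele_counts(gt)
  g <- cfg_get(cfg, "g", default_rarefaction_g(ac))
  stage("locus_table", emit(locus_diversity(gt), "locus_table.tsv"))
  gd <- stage("group_table", group_diversity(gt, g = g))
  emit(gd, "group_table.tsv")
  stage("nei", emit(nei_decomposition(ac), "nei_decomposition.tsv"))
  am <- stage("amova", amova(gt, n_perm = cfg_get(cfg, "n_perm", 199), seed = seed))
  emit(data.frame(source = c("among", "within"), df = am$df[1:2],
                  SS = am$SS[1:2], sigma2 = am$sigma2, percent = am$percent,
                  fst = am$fst, p = am$p_value), "amova.tsv")
  pw <- stage("pairwise_fst", pairwise_fst(gt))
  emit(data.frame(group = rownames(pw$fst), pw$fst, check.names = FALSE),
       "pairwise_fst.tsv")
  stage("chi2", emit(chi2_heterogeneity(ac), "chi2.tsv"))
  tr <- stage("tree", bootstrap_support(gt, n_reps = cfg_get(cfg, "boot_reps", 100),
                                        seed = seed))
  paths["tree.nwk"] <- write_newick(tr, file.path(out, "tree.nwk"))
  pca <- stage("pca", pca_genotypes(dosage_matrix(gt)))
  emit(data.frame(id = rownames(pca$scores), pca$scores, check.names = FALSE),
       "pca_scores.tsv")
  Ks <- cfg_get(cfg, "K_min", 2):cfg_get(cfg, "K_max", 6)
  scan <- stage("admixture",
                admixture_scan(gt, K_range = Ks, reps = cfg_get(cfg, "reps", 3),
                               seed = seed, burnin = cfg_get(cfg, "burnin", 100),
                               sweeps = cfg_get(cfg, "sweeps", 200)))
  for (K in Ks) {
    p <- file.path(out, sprintf("q_K%d.tsv", K))
    write_q_matrix(scan$best_runs[[as.character(K)]], p); stamp(p, hash)
    paths[basename(p)] <- p
  }
  emit(scan$evanno, "evanno.tsv")
  if (!is.null(gt$lon)) {
    cent <- stage("idw", {
      ar <- rarefied_allelic_richness(ac, g)
      par <- private_rarefied_richness(ac, g)
      gdg <- gd[gd$group != "Mean", ]
      agg <- aggregate(cbind(lon, lat) ~ group,
                       data.frame(group = gt$group, lon = gt$lon, lat = gt$lat),
                       mean)
      nc <- cfg_get(cfg, "idw_cells", 40)
      cs <- max(diff(range(gt$lon)), diff(range(gt$lat))) / nc
      tmpl <- grid_raster(matrix(0, nc, nc), min(gt$lon), min(gt$lat), cs)
      for (st in c("Ar", "PAr", "He")) {
        v <- gdg[[st]][match(agg$group, gdg$group)]
        p <- file.path(out, paste0("idw_", tolower(st), ".asc"))
        write_ascii_grid(idw_surface(agg, v, tmpl), p)
        paths[basename(p)] <- p
      }
      agg
    })
  }
  invisible(paths)
}

#' Run the niche-modeling track end to end
#'
#' Reads occurrences and a covariate stack; writes thinned occurrence sets,
#' the Gaussian bias grid, the correlation-pruned layer list, the tuning
#' table with Delta AICc, the selected model (JSON), the current prediction
#' raster, clamped projections onto each alternative stack and the pairwise
#' Schoener's D matrix over all prediction rasters.
#'
#' @param cfg list from [read_run_config()] (keys: `occurrences`, `stack_dir`,
#'   `out_dir`; optional `paleo_dirs`, `thin_km`, `n_bg`, `fc_set`, `rm_grid`,
#'   `n_knots`, `cor_threshold`, `seed`).
#' @return invisible named vector of output paths.
#' @export
run_enm <- function(cfg) {
  hash <- attr(cfg, "hash") %||% config_hash(cfg)
  out <- cfg_get(cfg, "out_dir", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg_get(cfg, "seed", 1)
  paths <- c()
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  read_stack <- function(d) {
    fs <- sort(list.files(d, pattern = "\\.asc$", full.names = TRUE))
    setNames(lapply(fs, read_ascii_grid), sub("\\.asc$", "", basename(fs)))
  }
  occ <- stage("read", {
    o <- read.table(cfg$occurrences, header = TRUE, sep = ",")
    occ_frame(o)
  })
  stack <- stage("stack", read_stack(cfg$stack_dir))
  keep <- stage("prune", correlation_prune(stack, cfg_get(cfg, "cor_threshold", 0.7)))
  writeLines(keep, file.path(out, "layers_retained.txt"))
  paths["layers_retained.txt"] <- file.path(out, "layers_retained.txt")
  stack <- stack[keep]
  occ_used <- occ
  for (r in cfg_get(cfg, "thin_km", numeric())) {
    th <- stage("thin", spatial_rarefy(occ, r))
    p <- file.path(out, sprintf("occ_thinned_%gkm.csv", r))
    write.table(th, p, sep = ",", row.names = FALSE, quote = FALSE)
    paths[basename(p)] <- p
    occ_used <- th
  }
  bias <- stage("bias", gaussian_bias_grid(occ_used, stack[[1]]))
  paths["bias.asc"] <- write_ascii_grid(bias, file.path(out, "bias.asc"))
  fc_set <- cfg_get(cfg, "fc_set", c("L", "LQ", "H", "LQH", "LQHP", "LQHPT"))
  tn <- stage("tune",
              tune_enm(occ_used, stack, n_bg = cfg_get(cfg, "n_bg", 10000),
                       fc_set = fc_set,
                       rm_grid = cfg_get(cfg, "rm_grid", seq(1, 5, 0.5)),
                       bias = bias, n_knots = cfg_get(cfg, "n_knots", 50),
                       seed = seed))
  p <- file.path(out, "tuning_table.tsv")
  write_tsv_table(tn$table, p); stamp(p, hash); paths["tuning_table.tsv"] <- p
  paths["model.json"] <- write_maxent_json(tn$best, file.path(out, "model.json"))
  preds <- list(current = stage("predict", project_model(tn$best, stack)))
  paths["pred_current.asc"] <- write_ascii_grid(preds$current,
                                                file.path(out, "pred_current.asc"))
  for (pd in cfg_get(cfg, "paleo_dirs", character())) {
    nm <- basename(pd)
    st <- stage("project", read_stack(pd)[names(stack)])
    preds[[nm]] <- project_model(tn$best, st, clamp = TRUE)
    p <- file.path(out, sprintf("pred_%s.asc", nm))
    write_ascii_grid(preds[[nm]], p)
    paths[basename(p)] <- p
  }
  D <- stage("overlap", schoener_d_matrix(preds))
  p <- file.path(out, "schoener_d.tsv")
  write_tsv_table(data.frame(model = rownames(D), D, check.names = FALSE), p)
  stamp(p, hash); paths["schoener_d.tsv"] <- p
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimal command-line entry point
#'
#' Subcommands: `genetics <config>`, `enm <config>`, `simulate <dir> [seed]`,
#' `overlap <r1.asc> <r2.asc>`.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly.
#' @export
refugia_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: refugia <genetics|enm|simulate|overlap> ..."
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  switch(cmd,
    genetics = run_genetics(read_run_config(rest[1])),
    enm = run_enm(read_run_config(rest[1])),
    simulate = {
      seed <- if (length(rest) > 1) as.integer(rest[2]) else 1L
      sim <- simulate_genotypes(genotype_sim_spec(seed = seed))
      land <- simulate_landscape(landscape_sim_spec(seed = seed))
      occ <- sample_occurrences(land$suitability, 300, seed = seed)
      write_sim_fixtures(rest[1], gt = sim$gt, occ = occ,
                         stack = c(land$stack,
                                   list(suitability = land$suitability)))
    },
    overlap = {
      d <- schoener_d(read_ascii_grid(rest[1]), read_ascii_grid(rest[2]))
      cat(format(d, digits = 6), "\n")
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}
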