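#' Default pipeline run configuration
#'
#' Parameter defaults encode the analysis conventions the package is built
#' around: LD expansion at r2 = 0.8 within +/- 5,000 bp, protein
#' interactions at confidence >= 0.7, four network expansion levels, 1,000
#' bootstrap iterations, exposure instruments at p <= 1e-5, MAF >= 0.05,
#' and BH-adjusted eQTL significance at 0.05. Two tissue contexts
#' ("fetal", "adult") run as independent simulations whose discovered
#' traits are compared at the end.
#'
#' @param outdir output directory
#' @param seed master seed; per-tissue and per-stage seeds are derived
#'   from it
#' @return a `run_config` list
#' @export
default_run_config <- function(outdir = tempfile("pleionet_run_"),
                               seed = 1) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    tissues = c("fetal", "adult"),
    sim = list(n_chromosomes = 2, chromosome_length = 1e6,
               fragment_bp = 4000, n_genes = 40, n_snps = 300,
               n_true_eqtls = 20, causal_gene_instruments = 5,
               causal_theta = 0.5),
    catalog = list(n_traits = 30, pleiotropy_frac = 0.8,
                   n_pleiotropic = 1, trait_size = 20),
    grn = list(maf_min = 0.05, alpha = 0.05, include_same_fragment = TRUE),
    ld = list(r2_min = 0.8, width_bp = 5000),
    discovery = list(min_score = 0.7, max_level = 4, alpha = 0.05,
                     n_iter = 200, bootstrap_threshold = 0.01),
    mr = list(p_max = 1e-5, alpha = 0.05, clump_r2 = 0.001,
              clump_window_bp = 1e7, se_y = 0.05),
    comorbidity = list(n_individuals = 50000, index_prevalence = 0.01,
                       alpha = 0.05, correction = "BH",
                       or_map = list(F200 = 4, J449 = 1, E660 = 2,
                                     G309 = 1, M545 = 1),
                       base_rates = list(F200 = 0.05, J449 = 0.08,
                                         E660 = 0.05, G309 = 0.03,
                                         M545 = 0.1))
  ), class = "run_config")
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  probs <- c(grn_alpha = config$grn$alpha,
             discovery_alpha = config$discovery$alpha,
             bootstrap_threshold = config$discovery$bootstrap_threshold,
             mr_alpha = config$mr$alpha,
             comorbidity_alpha = config$comorbidity$alpha,
             ld_r2_min = config$ld$r2_min,
             min_score = config$discovery$min_score)
  bad <- names(probs)[probs <= 0 | probs > 1]
  if (length(bad)) {
    stop_config("threshold(s) outside (0, 1]: ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(config$seed) || config$seed != round(config$seed)) {
    stop_config("seed must be an integer")
  }
  invisible(config)
}

#' Read a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; a parse-serialise-parse round trip is the
#' identity.
#'
#' @param path configuration file (.yaml/.yml or .json)
#' @return a validated `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(unclass(default_run_config()), raw)
  cfg$tissues <- unlist(cfg$tissues)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Write a run configuration to YAML or JSON
#' @param config a `run_config`
#' @param path destination (.yaml/.yml or .json)
#' @return invisibly, `path`
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Validate pipeline input files against their column schemas
#'
#' Checks every supplied file against its expected columns plus basic
#' coordinate sanity (start < end, positions >= 0), allele alphabet, and
#' value-range rules. The report lists all violations, not just the
#' first; an empty report means a well-formed bundle.
#'
#' @param paths named list/vector of file paths; recognised names:
#'   fragments (BED), snps, genes (GFF3), contacts, assoc, catalog, ppin,
#'   gene_protein_map, admissions
#' @return data.frame (file, message); zero rows when everything passes
#' @export
validate_inputs <- function(paths) {
  report <- list()
  note <- function(file, msg) {
    report[[length(report) + 1L]] <<- data.frame(
      file = file, message = msg, stringsAsFactors = FALSE)
  }
  for (kind in names(paths)) {
    path <- paths[[kind]]
    if (!file.exists(path)) { note(kind, "file does not exist"); next }
    ok_read <- TRUE
    df <- tryCatch(switch(kind,
      fragments = {
        b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
        names(b)[1:4] <- c("chrom", "start", "end", "fragment_id"); b
      },
      genes = read_genes_gff3(path),
      read_tsv(path)
    ), error = function(e) { ok_read <<- FALSE; note(kind, paste("unreadable:", conditionMessage(e))); NULL })
    if (!ok_read) next
    need <- switch(kind,
      fragments = c("chrom", "start", "end", "fragment_id"),
      snps = c("snp_id", "chrom", "pos", "ref", "alt", "maf"),
      genes = c("gene_id", "chrom", "start", "end"),
      contacts = c("fragment_a", "fragment_b"),
      assoc = c("snp_id", "gene_id", "beta", "se", "p"),
      catalog = c("trait", "snp"),
      ppin = c("protein_a", "protein_b", "score"),
      gene_protein_map = c("gene_id", "protein_id"),
      admissions = c("person_id", "icd10_code"),
      character(0))
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      note(kind, paste("missing column(s):", paste(miss, collapse = ", ")))
      next
    }
    if (kind %in% c("fragments", "genes")) {
      if (any(df$start >= df$end)) note(kind, "interval(s) with start >= end")
      if (any(df$start < 0)) note(kind, "negative start coordinate(s)")
    }
    if (kind == "snps") {
      if (any(df$pos < 0)) note(kind, "negative SNP position(s)")
      if (!all(grepl("^[ACGT]+$", df$ref)) || !all(grepl("^[ACGT]+$", df$alt))) {
        note(kind, "allele(s) outside the ACGT alphabet")
      }
      if (any(df$maf < 0 | df$maf > 1)) note(kind, "MAF outside [0, 1]")
    }
    if (kind == "assoc") {
      if (any(df$se <= 0)) note(kind, "association row(s) with se <= 0")
      if (any(df$p < 0 | df$p > 1)) note(kind, "p-value(s) outside [0, 1]")
    }
    if (kind == "ppin" && any(df$score < 0 | df$score > 1)) {
      note(kind, "interaction score(s) outside [0, 1]")
    }
    if (kind == "admissions") {
      if (any(!grepl("^[A-Z][0-9]", df$icd10_code))) {
        note(kind, "ICD-10 code(s) not matching letter+digits pattern")
      }
      if (any(!nzchar(df$person_id))) note(kind, "empty person_id(s)")
    }
  }
  if (length(report)) do.call(rbind, report) else
    data.frame(file = character(0), message = character(0))
}

run_stage <- function(manifest, name, fn) {
  t0 <- proc.time()[["elapsed"]]
  value <- fn()
  manifest$stages[[name]] <- list(
    status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
  list(manifest = manifest, value = value)
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in dependency order, per tissue: simulate the world
#' and its tables, build the spatial GRN, LD-expand the query SNPs,
#' discover pleiotropic traits through the protein network with the
#' bootstrap null, and estimate per-gene causal effects by two-sample MR.
#' The admissions/comorbidity stage runs once (it is population-level,
#' not tissue-level), and a final comparison reports traits shared
#' between the two tissue contexts. Identical config and seed reproduce
#' identical stage outputs byte for byte (the manifest, which records
#' wall times, is the one file excluded from that guarantee).
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()])
#' @return invisibly, a list with per-tissue results, the comorbidity
#'   table, the tissue comparison, and the manifest (also written to
#'   `<outdir>/manifest.json`)
#' @export
run_all <- function(config = default_run_config()) {
  validate_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   version = as.character(utils::packageVersion("pleionet")),
                   stages = list(), files = list())
  results <- list(tissues = list())
  finalize <- function() {
    paths <- unlist(manifest$files, use.names = FALSE)
    if (length(paths)) {
      manifest$files <- lapply(manifest$files, function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    }
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }
  on.exit(manifest <- finalize())

  for (ti in seq_along(config$tissues)) {
    tissue <- config$tissues[ti]
    tseed <- child_seed(config$seed, ti)
    tdir <- function(stage) {
      d <- file.path(config$outdir, tissue, stage)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      d
    }
    # -- simulate ------------------------------------------------------
    st <- run_stage(manifest, paste0(tissue, "/simulate"), function() {
      scfg <- do.call(sim_config, config$sim)
      world <- gen_world(scfg, tseed)
      assoc <- gen_eqtl_table(world, seed = child_seed(tseed, 1))
      catalog <- do.call(gen_gwas_catalog, c(
        list(world = world, seed = child_seed(tseed, 2)), config$catalog))
      world$truth$pleiotropic_loci <- attr(catalog, "planted")
      d <- tdir("simulate")
      paths <- write_world(world, d)
      paths <- c(paths, assoc = write_tsv(assoc, file.path(d, "assoc.tsv")),
                 catalog = write_tsv(catalog, file.path(d, "catalog.tsv")))
      list(world = world, assoc = assoc, catalog = catalog, paths = paths)
    })
    manifest <- st$manifest
    sim <- st$value
    manifest$files[[paste0(tissue, "_simulate")]] <- unname(sim$paths)

    # -- build-grn -----------------------------------------------------
    st <- run_stage(manifest, paste0(tissue, "/grn"), function() {
      grn <- build_grn(sim$world, sim$assoc,
                       maf_min = config$grn$maf_min,
                       alpha = config$grn$alpha,
                       include_same_fragment = config$grn$include_same_fragment,
                       tissue = tissue)
      write_tsv(as.data.frame(grn), file.path(tdir("grn"), "grn.tsv"))
      grn
    })
    manifest <- st$manifest
    grn <- st$value
    manifest$files[[paste0(tissue, "_grn")]] <-
      file.path(config$outdir, tissue, "grn", "grn.tsv")

    # -- expand-ld -----------------------------------------------------
    ld <- ld_resource(sim$world$ld,
                      sim$world$snps[c("snp_id", "chrom", "pos")])
    st <- run_stage(manifest, paste0(tissue, "/expand_ld"), function() {
      exp <- expand_ld(sim$world$truth$query_snps, ld,
                       r2_min = config$ld$r2_min,
                       width_bp = config$ld$width_bp)
      write_tsv(exp, file.path(tdir("expand_ld"), "expanded_query.tsv"))
      exp
    })
    manifest <- st$manifest
    expanded <- st$value
    manifest$files[[paste0(tissue, "_expand_ld")]] <-
      file.path(config$outdir, tissue, "expand_ld", "expanded_query.tsv")

    # -- discover ------------------------------------------------------
    st <- run_stage(manifest, paste0(tissue, "/discover"), function() {
      ppin <- ppin_graph(sim$world$ppin, sim$world$gene_protein_map,
                         min_score = config$discovery$min_score)
      cfg <- bootstrap_config(
        n_iter = config$discovery$n_iter,
        resample_size = length(unique(expanded$snp_id)),
        seed = child_seed(tseed, 3),
        threshold = config$discovery$bootstrap_threshold)
      disc <- discover_traits(expanded$snp_id, grn, ppin, sim$catalog,
                              alpha = config$discovery$alpha,
                              max_level = config$discovery$max_level,
                              bootstrap_cfg = cfg)
      d <- tdir("discover")
      write_tsv(disc$table, file.path(d, "discovery.tsv"))
      jsonlite::write_json(
        list(n_level_genes = vapply(disc$levels$genes, length, integer(1)),
             n_traits_retained = nrow(disc$enrichment)),
        file.path(d, "discovery_summary.json"), auto_unbox = TRUE)
      disc
    })
    manifest <- st$manifest
    disc <- st$value
    manifest$files[[paste0(tissue, "_discover")]] <-
      file.path(config$outdir, tissue, "discover", "discovery.tsv")

    # -- mr ------------------------------------------------------------
    st <- run_stage(manifest, paste0(tissue, "/mr"), function() {
      exposure <- grn_exposures(grn, sim$world$snps)
      outcome <- gen_outcome_stats(exposure, sim$world$truth$causal_genes,
                                   se_y = config$mr$se_y,
                                   seed = child_seed(tseed, 4))
      mr <- run_2smr(exposure, outcome, ld = ld,
                     p_max = config$mr$p_max, alpha = config$mr$alpha,
                     clump_r2 = config$mr$clump_r2,
                     clump_window_bp = config$mr$clump_window_bp)
      write_tsv(mr, file.path(tdir("mr"), "mr_results.tsv"))
      mr
    })
    manifest <- st$manifest
    mr <- st$value
    manifest$files[[paste0(tissue, "_mr")]] <-
      file.path(config$outdir, tissue, "mr", "mr_results.tsv")

    results$tissues[[tissue]] <- list(world = sim$world, assoc = sim$assoc,
                                      catalog = sim$catalog, grn = grn,
                                      expanded = expanded,
                                      discovery = disc, mr = mr)
  }

  # -- comorbidity (population level, once) ----------------------------
  st <- run_stage(manifest, "comorbidity", function() {
    cm <- config$comorbidity
    adm <- gen_admissions(cm$n_individuals, cm$index_prevalence,
                          unlist(cm$or_map), unlist(cm$base_rates),
                          seed = child_seed(config$seed, 99))
    res <- run_comorbidity(adm, index_codes = "F840", alpha = cm$alpha,
                           correction = cm$correction)
    d <- file.path(config$outdir, "comorbidity")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_tsv(adm, file.path(d, "admissions.tsv"))
    write_tsv(res, file.path(d, "cooccurrence.tsv"))
    list(admissions = adm, result = res)
  })
  manifest <- st$manifest
  results$comorbidity <- st$value
  manifest$files[["comorbidity"]] <-
    file.path(config$outdir, "comorbidity", "cooccurrence.tsv")

  # -- tissue comparison ----------------------------------------------
  if (length(config$tissues) >= 2) {
    t1 <- results$tissues[[config$tissues[1]]]$discovery$enrichment
    t2 <- results$tissues[[config$tissues[2]]]$discovery$enrichment
    s1 <- unique(t1$trait); s2 <- unique(t2$trait)
    comparison <- list(
      tissue_a = config$tissues[1], tissue_b = config$tissues[2],
      n_a = length(s1), n_b = length(s2),
      n_shared = length(intersect(s1, s2)),
      shared = sort(intersect(s1, s2)),
      only_a = sort(setdiff(s1, s2)), only_b = sort(setdiff(s2, s1)))
    jsonlite::write_json(comparison,
                         file.path(config$outdir, "trait_comparison.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    results$comparison <- comparison
  }

  results$manifest <- finalize()
  on.exit()
  invisible(results)
}
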