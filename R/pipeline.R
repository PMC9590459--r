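# End-to-end orchestration: a flat JSON config drives
# read -> weights -> PSSM -> Potts -> environment -> enumerate -> cluster ->
# representatives (design), or EIC -> areas -> curves -> yields ->
# percentages (quantification). Reports embed the parameter set and input
# content hashes for auditability.

design_defaults <- list(
  alignment_format = "fasta", identity_threshold = 0.8,
  pseudocount_alpha = 1.0, lambda_h = 0.01, lambda_J = NA,
  max_iter = 500, tol = 1e-3, potts_alphabet = "full",
  k_pairs = NA, surface_min = 0.25, buried_max = 0.05,
  pocket_cutoff = 6.0, probe = 1.4, n_points = 960,
  cluster_k = 8, filter = "all", base_variant = "", seed = 1,
  ligand_codes = "HEM")

#' Load a run configuration
#'
#' @param config Path to a flat JSON file, or a named list. Unknown keys
#'   error; missing keys take the documented defaults.
#' @param defaults Default list to merge into.
#' @return Named list of parameters.
#' @export
load_config <- function(config, defaults = design_defaults) {
  cfg <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  unknown <- setdiff(names(cfg),
                     c(names(defaults), "alignment", "structure", "target",
                       "aliases", "out_dir", "external_scores",
                       "spectra", "curve_points", "compounds"))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, as.list(cfg))
}

input_hash <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  vapply(paths, function(p) unname(tools::md5sum(p)), character(1))
}

#' Run the full variant-design pipeline
#'
#' Reads the alignment and structure named in the config, computes sequence
#' weights, the PSSM and the Potts coupling map, classifies residues by
#' solvent accessibility and pocket membership, enumerates candidate
#' variants from both evidence streams, clusters them with PAM30 distances
#' and selects the lowest-scored representative per cluster. Writes the
#' candidate table (`candidates.tsv`) and a JSON report to `out_dir` when
#' given.
#'
#' Required config keys: `alignment` (path), `target` (sequence string whose
#' length equals the alignment width). Optional: `structure` (PDB path),
#' `base_variant` (name string), `aliases` (named list), `out_dir`, plus the
#' numeric parameters documented in the package vignette.
#'
#' @param config Path to a JSON config or a named list.
#' @return Object of class `DesignReport`: `candidates` (`VariantSet`),
#'   `clusters`, `representatives`, `pssm_subs`, `coev_subs`, `environment`,
#'   `provenance` (parameter echo, neff, convergence, input hashes).
#' @export
run_design <- function(config) {
  cfg <- load_config(config)
  stage <- "config"
  fail <- function(e) stop(sprintf("stage '%s' failed: %s", stage,
                                   conditionMessage(e)), call. = FALSE)
  tryCatch({
    stage <- "seq_conservation"
    if (is.null(cfg$alignment)) stop("config key 'alignment' is required")
    if (is.null(cfg$target)) stop("config key 'target' is required")
    aln <- read_alignment(cfg$alignment, cfg$alignment_format)
    w <- compute_weights(aln, cfg$identity_threshold)
    pssm <- compute_pssm(aln, w, alpha = cfg$pseudocount_alpha)
    base_variant <- parse_variant_name(cfg$base_variant, cfg$target,
                                       aliases = cfg$aliases)
    target_seq <- apply_variant(base_variant)
    pssm_subs <- positive_substitutions(pssm, target_seq)

    stage <- "coevolution"
    lambda_J <- if (is.na(cfg$lambda_J)) 0.2 * (aln$L - 1) else cfg$lambda_J
    model <- fit_potts(aln, w, lambda_h = cfg$lambda_h, lambda_J = lambda_J,
                       max_iter = cfg$max_iter, tol = cfg$tol,
                       alphabet = cfg$potts_alphabet)
    scores <- coupling_scores(model)
    k_pairs <- if (is.na(cfg$k_pairs)) ceiling(1.5 * aln$L) else cfg$k_pairs
    coev_subs <- coevolved_substitutions(model, scores, target_seq,
                                         k_pairs = k_pairs)

    stage <- "structure_env"
    env <- NULL
    if (!is.null(cfg$structure)) {
      s <- read_structure(cfg$structure, ligand_codes = cfg$ligand_codes)
      areas <- atom_sasa(s, probe = cfg$probe, n_points = cfg$n_points)
      rsa <- residue_rsa(s, areas)
      env <- classify_residues(s, rsa, surface_min = cfg$surface_min,
                               buried_max = cfg$buried_max,
                               pocket_cutoff = cfg$pocket_cutoff)
    }

    stage <- "variant_design"
    vs <- enumerate_candidates(base_variant, pssm_subs, coev_subs, env,
                               filter = cfg$filter)
    if (!is.null(cfg$external_scores)) {
      ext <- utils::read.table(cfg$external_scores, header = TRUE, sep = "\t")
      m <- match(vs$table$name, ext$name)
      hit <- !is.na(m)
      vs$table$score[hit] <- ext$score[m[hit]]
      for (i in which(hit)) vs$variants[[i]]$score <- ext$score[m[i]]
    }
    k <- min(cfg$cluster_k, length(vs$variants))
    ca <- cluster_variants(vs, k = k)
    reps <- select_representatives(ca)

    stage <- "report"
    prov <- list(parameters = cfg, neff = w$neff, L = aln$L, N = aln$N,
                 potts_converged = model$converged,
                 potts_grad_norm = model$grad_norm,
                 input_hashes = as.list(
                   input_hash(c(alignment = cfg$alignment,
                                structure = cfg$structure))))
    rep_obj <- structure(list(candidates = vs, clusters = ca,
                              representatives = reps,
                              pssm_subs = pssm_subs, coev_subs = coev_subs,
                              environment = env, provenance = prov),
                         class = "DesignReport")
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_variant_report(vs, ca, file.path(cfg$out_dir, "candidates.tsv"))
      jsonlite::write_json(
        list(provenance = prov,
             representatives = vapply(reps, `[[`, character(1), "name")),
        file.path(cfg$out_dir, "design_report.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
    }
    rep_obj
  }, error = fail)
}

#' @export
print.DesignReport <- function(x, ...) {
  cat(sprintf(
    "DesignReport: %d candidates -> %d clusters; neff %.1f; Potts %s\n",
    length(x$candidates$variants), x$clusters$k, x$provenance$neff,
    if (x$provenance$potts_converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Run the quantification pipeline
#'
#' Extracts one EIC per configured compound, integrates the peak in its
#' retention window, fits (or reuses) standard curves and reports yields and
#' normalized product percentages, one row per compound.
#'
#' Config keys: `spectra` (CSV path or `SpectraSeries`), `compounds` (list:
#' each with `name`, `formula`, `adduct`, `rt_window` = c(from, to), and
#' optional `curve` naming the compound whose standard curve to share),
#' `curve_points` (named list of data.frames with `concentration`, `area`),
#' optional `tol_ppm` (default 20) and `out_dir`.
#'
#' @param config Path to a JSON config or a named list.
#' @return data.frame `compound`, `mz`, `area`, `yield`, `percentage`.
#' @export
run_quantify <- function(config) {
  cfg <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = FALSE)
  } else config
  stage <- "config"
  fail <- function(e) stop(sprintf("stage '%s' failed: %s", stage,
                                   conditionMessage(e)), call. = FALSE)
  tryCatch({
    if (is.null(cfg$spectra)) stop("config key 'spectra' is required")
    if (is.null(cfg$compounds)) stop("config key 'compounds' is required")
    tol_ppm <- if (is.null(cfg$tol_ppm)) 20 else cfg$tol_ppm
    stage <- "metabolite_quant"
    s <- if (inherits(cfg$spectra, "SpectraSeries")) cfg$spectra else
      read_spectra_csv(cfg$spectra)
    curves <- lapply(cfg$curve_points, function(p)
      fit_standard_curve(as.data.frame(p)))
    areas <- numeric(0)
    mzs <- numeric(0)
    cmap <- character(0)
    for (cp in cfg$compounds) {
      mz <- adduct_mz(cp$formula, cp$adduct)
      eic <- extract_eic(s, mz, tol_ppm)
      areas[[cp$name]] <- integrate_peak(eic, unlist(cp$rt_window))
      mzs[[cp$name]] <- mz
      cmap[[cp$name]] <- if (is.null(cp$curve)) cp$name else cp$curve
    }
    qn <- quantify_and_normalize(areas, curves, shared_curve_map = cmap)
    out <- data.frame(compound = names(areas), mz = round(unname(mzs), 4),
                      area = unname(areas), yield = unname(qn$yields),
                      percentage = unname(qn$percentages))
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(out, file.path(cfg$out_dir, "quantification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  }, error = fail)
}
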