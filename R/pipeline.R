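#' Default pipeline configuration
#'
#' Returns the full default config as a named list; user configs (YAML)
#' are validated against this schema — unknown keys are rejected — and
#' merged over it. Sizes are bp throughout.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "dsbchrom_out",
    stages = c("simulate", "hic", "insulation", "chip", "asymmetry",
               "boundary", "bands"),
    simulation = list(n_sites = 30, min_separation = 1e6, edge_margin = 2e6,
                      params = list()),
    inputs = NULL,
    hic = list(half_width = 1.5e6, epsilon = 1, v4c_flank = 1.4e6,
               v4c_mode = "center"),
    insulation = list(square_size = 5e5, window = 5e4,
                      enrichment_window = 2e4),
    chip = list(fine_half_width = 1.5e4, fine_bin = 100,
                coarse_half_width = 1.5e6, coarse_bin = 5e3,
                asym_half_width = 5e3, asym_bin = 200,
                asym_threshold = 0.1),
    boundary = list(dist_range = c(2e5, 7e5), flank = 1e5, n_controls = 100),
    bands = list(bands = list(c(-1.5e6, 5e5), c(5e5, 1.5e6)),
                 broadening = 1.5)
  )
}

#' Read and validate a pipeline config
#'
#' @param path YAML config file, or a named list.
#' @return validated config list merged over [default_config()].
#' @export
read_config <- function(path) {
  user <- if (is.character(path)) yaml::yaml.load_file(path) else path
  def <- default_config()
  check_keys <- function(u, d, where) {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop_data("unknown config key", if (length(unknown) > 1) "s", " ",
                paste0(where, unknown, collapse = ", "))
  }
  check_keys(user, def, "")
  for (k in intersect(names(user), c("simulation", "hic", "insulation",
                                     "chip", "boundary", "bands")))
    check_keys(user[[k]], def[[k]], paste0(k, "/"))
  cfg <- modifyList(def, user)
  if (!is.null(user$stages)) cfg$stages <- unlist(user$stages)
  bad <- setdiff(cfg$stages, default_config()$stages)
  if (length(bad)) stop_data("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(user$simulation$params$genome))
    cfg$simulation$params$genome <- unlist(user$simulation$params$genome)
  if (!is.null(user$bands$bands))
    cfg$bands$bands <- lapply(user$bands$bands, unlist)
  if (!is.null(user$boundary$dist_range))
    cfg$boundary$dist_range <- unlist(user$boundary$dist_range)
  cfg
}

#' Run the break-centered chromatin pipeline
#'
#' Executes the requested stages in dependency order on simulated data:
#' `simulate` (sites, boundaries, contact-map pair, ChIP pair),
#' `hic` (windowed differential aggregate map + cut-centered differential
#' virtual 4C), `insulation` (per-chromosome tracks, per-site insulation
#' change, correlation with ChIP enrichment), `chip` (fine+coarse
#' meta-profiles and the two-component width fit), `asymmetry`
#' (strand asymmetry profile), `boundary` (TAD-boundary drop with random
#' controls) and `bands` (distance-band comparison against a
#' broadened-domain second condition). All randomness derives from the
#' config seed, so a rerun with the same config is byte-identical
#' (the report carries no timestamps). Outputs are written under
#' `out_dir`: BED6 sites/boundaries, dense contact TSVs, bedGraph
#' coverage, profile/table TSVs, the truth record and `report.yaml`.
#'
#' @param config a config list or YAML path ([read_config()]).
#' @param quiet suppress progress messages.
#' @return a `run_report` (invisibly): nested list of per-stage summary
#'   statistics plus provenance.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[dsbchrom] ", ...)
  report <- list(stages = list())
  stage <- function(name, expr) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    say("stage ", name)
    tryCatch(expr, error = function(e)
      stop_data("stage ", name, " failed: ", conditionMessage(e)))
  }

  ## provenance: hash of the canonical config serialization (analysis
  ## parameters only; the output location does not change the analysis)
  canon <- tempfile(fileext = ".yaml")
  cfg_hash <- cfg; cfg_hash$out_dir <- NULL
  writeLines(yaml::as.yaml(cfg_hash, precision = 15L), canon)
  report$provenance <- list(
    config_hash = unname(tools::md5sum(canon)),
    package_version = as.character(utils::packageVersion("dsbchrom")),
    seed = cfg$seed)
  unlink(canon)

  ## --- simulate / load inputs ----------------------------------------
  needs_hic <- any(c("simulate", "hic", "insulation") %in% cfg$stages)
  needs_chip <- any(c("simulate", "insulation", "chip", "asymmetry",
                      "boundary", "bands") %in% cfg$stages)
  hic <- chip <- chipB_in <- NULL
  if (!is.null(cfg$inputs)) {
    say("loading provided inputs")
    inp <- cfg$inputs
    sites <- read_sites_bed(inp$sites)
    boundaries <- if (!is.null(inp$boundaries)) {
      b <- read_sites_bed(inp$boundaries)
      data.frame(chrom = b$chrom, pos = b$pos, stringsAsFactors = FALSE)
    } else data.frame(chrom = character(), pos = numeric())
    read_maps <- function(paths) {
      m <- lapply(paths, read_contact_map)
      stats::setNames(m, vapply(m, `[[`, "", "chrom"))
    }
    read_covs <- function(prefixes) {
      cv <- lapply(prefixes, read_coverage_bedgraph)
      stats::setNames(cv, vapply(cv, `[[`, "", "chrom"))
    }
    if (needs_hic && !is.null(inp$contact_treated))
      hic <- list(treated = read_maps(inp$contact_treated),
                  untreated = read_maps(inp$contact_untreated))
    if (needs_chip && !is.null(inp$coverage_treated))
      chip <- list(treated = read_covs(inp$coverage_treated),
                   untreated = read_covs(inp$coverage_untreated))
    if (!is.null(inp$coverage_B_treated))
      chipB_in <- list(treated = read_covs(inp$coverage_B_treated),
                       untreated = read_covs(inp$coverage_B_untreated))
    needs_hic <- needs_hic && !is.null(hic)
    needs_chip <- needs_chip && !is.null(chip)
    sp <- NULL
  } else {
    sp <- do.call(sim_params, c(cfg$simulation$params, list(seed = cfg$seed)))
    made <- make_sites(sp, cfg$simulation$n_sites,
                       cfg$simulation$min_separation,
                       cfg$simulation$edge_margin)
    sites <- made$sites
    boundaries <- made$boundaries
    if (needs_hic) {
      say("simulating contact maps")
      hic <- simulate_contact_pair(sp, sites)
    }
    if (needs_chip) {
      say("simulating ChIP coverage")
      chip <- simulate_chip_pair(sp, sites, boundaries)
    }
    stage("simulate", {
      write_sites_bed(sites, file.path(cfg$out_dir, "sites.bed"))
      write_sites_bed(boundaries, file.path(cfg$out_dir, "boundaries.bed"))
      write_truth(hic$truth %||% chip$truth,
                  file.path(cfg$out_dir, "truth.yaml"))
      for (ch in names(sp$genome)) {
        write_contact_map(hic$treated[[ch]],
                          file.path(cfg$out_dir, paste0("contacts_treated_", ch, ".tsv")))
        write_contact_map(hic$untreated[[ch]],
                          file.path(cfg$out_dir, paste0("contacts_untreated_", ch, ".tsv")))
        write_coverage_bedgraph(chip$treated[[ch]],
                                file.path(cfg$out_dir, paste0("chip_treated_", ch)))
        write_coverage_bedgraph(chip$untreated[[ch]],
                                file.path(cfg$out_dir, paste0("chip_untreated_", ch)))
      }
      report$stages$simulate <- list(
        n_sites = nrow(sites), n_boundaries = nrow(boundaries),
        contact_total_treated = sum(vapply(hic$treated, function(m)
          sum(m$counts[upper.tri(m$counts, diag = TRUE)]), numeric(1))),
        chip_library_treated = chip$treated[[1]]$library_size,
        warnings = as.list(chip$truth$warnings))
    })
  }

  enrich <- if (needs_chip) enrichment_track(chip$treated, chip$untreated)

  ## --- hic ------------------------------------------------------------
  stage("hic", {
    wt <- extract_windows(hic$treated, sites, cfg$hic$half_width)
    wu <- extract_windows(hic$untreated, sites, cfg$hic$half_width)
    agg <- differential_map(wt, wu, cfg$hic$epsilon)
    write_aggregate_tsv(agg, file.path(cfg$out_dir, "differential_map.tsv"))
    ctr <- (nrow(agg$matrix) + 1) / 2
    cross <- c(agg$matrix[ctr, -ctr], agg$matrix[-ctr, ctr])
    off <- agg$matrix[-ctr, -ctr]
    v4c <- site_differential_4c(hic$treated, hic$untreated, sites,
                                cfg$hic$v4c_flank,
                                viewpoint_mode = cfg$hic$v4c_mode)
    write_profile_tsv(structure(list(dist = v4c$dist, value = v4c$value,
                                     n_sites = nrow(sites)),
                                class = "meta_profile"),
                      file.path(cfg$out_dir, "differential_4c.tsv"))
    report$stages$hic <- list(
      n_windows = agg$n, epsilon = agg$epsilon,
      cross_mean_log2 = mean(cross, na.rm = TRUE),
      off_cross_mean_log2 = mean(off, na.rm = TRUE),
      center_log2 = agg$matrix[ctr, ctr],
      v4c_max_excess = max(v4c$value, na.rm = TRUE))
  })

  ## --- insulation -----------------------------------------------------
  stage("insulation", {
    it <- lapply(hic$treated, insulation_score, square_size = cfg$insulation$square_size)
    iu <- lapply(hic$untreated, insulation_score, square_size = cfg$insulation$square_size)
    dis <- delta_insulation(it, iu, sites, cfg$insulation$window)
    write_table_tsv(dis$per_site, file.path(cfg$out_dir, "delta_insulation.tsv"),
                    meta = c(window = dis$window, n = dis$n))
    rep_ins <- list(n = dis$n, mean_dIS = dis$mean, sem = dis$sem,
                    t = dis$t, p = dis$p,
                    frac_negative = mean(dis$per_site$dIS < 0))
    if (needs_chip) {
      enr <- site_enrichment(enrich, sites, cfg$insulation$enrichment_window)
      keep <- match(dis$per_site$site_id, paste0(sites$chrom, ":", sites$pos))
      cr <- correlate_enrichment(dis$per_site$drop, enr[keep])
      write_table_tsv(data.frame(site_id = dis$per_site$site_id,
                                 drop = dis$per_site$drop,
                                 enrichment = enr[keep]),
                      file.path(cfg$out_dir, "drop_vs_enrichment.tsv"))
      rep_ins$spearman_rho <- cr$rho
      rep_ins$spearman_p <- cr$p
    }
    report$stages$insulation <- rep_ins
  })

  ## --- chip -----------------------------------------------------------
  fit <- NULL
  stage("chip", {
    fine <- meta_profile(chip$treated, chip$untreated, sites,
                         cfg$chip$fine_half_width, cfg$chip$fine_bin)
    coarse <- meta_profile(chip$treated, chip$untreated, sites,
                           cfg$chip$coarse_half_width, cfg$chip$coarse_bin)
    write_profile_tsv(fine, file.path(cfg$out_dir, "meta_profile_fine.tsv"))
    write_profile_tsv(coarse, file.path(cfg$out_dir, "meta_profile_coarse.tsv"))
    fit <- fit_two_component(fine, coarse)
    report$stages$chip <- list(
      n_sites = fine$n_sites,
      narrow_fwhm_bp = fit$narrow_fwhm, narrow_fwhm_se_bp = fit$narrow_fwhm_se,
      broad_fwhm_bp = fit$broad_fwhm, broad_fwhm_se_bp = fit$broad_fwhm_se,
      background = fit$background, converged = fit$converged)
  })

  ## --- asymmetry ------------------------------------------------------
  stage("asymmetry", {
    asym <- strand_asymmetry(chip$treated, chip$untreated, sites,
                             cfg$chip$asym_half_width, cfg$chip$asym_bin,
                             cfg$chip$asym_threshold)
    write_profile_tsv(asym, file.path(cfg$out_dir, "strand_asymmetry.tsv"))
    report$stages$asymmetry <- list(
      extent_bp = asym$extent, switch_pos_bp = asym$switch_pos,
      mean_left = mean(asym$value[asym$dist < 0]),
      mean_right = mean(asym$value[asym$dist > 0]))
  })

  ## --- boundary -------------------------------------------------------
  stage("boundary", {
    bd <- boundary_drop(enrich, sites, boundaries,
                        cfg$boundary$dist_range, cfg$boundary$flank,
                        n_controls = cfg$boundary$n_controls,
                        seed = derive_seed(cfg$seed, "controls"))
    write_table_tsv(data.frame(drop = bd$boundaries$drops),
                    file.path(cfg$out_dir, "boundary_drops.tsv"))
    report$stages$boundary <- list(
      n_pairs = bd$boundaries$n, mean_drop = bd$boundaries$mean,
      sem = bd$boundaries$sem, t = bd$boundaries$t, p = bd$boundaries$p,
      control_mean = bd$controls$mean, control_sem = bd$controls$sem,
      control_p = bd$controls$p, n_controls = bd$controls$n)
  })

  ## --- bands ----------------------------------------------------------
  stage("bands", {
    enrichB <- if (!is.null(chipB_in)) {
      enrichment_track(chipB_in$treated, chipB_in$untreated)
    } else {
      if (is.null(sp))
        stop_data("bands stage needs condition-B coverage inputs or a simulation spec")
      spB <- sp
      spB$broad_sd <- sp$broad_sd * cfg$bands$broadening
      spB$seed <- derive_seed(cfg$seed, "condB")
      chipB <- simulate_chip_pair(spB, sites, boundaries)
      enrichment_track(chipB$treated, chipB$untreated)
    }
    bd <- band_difference(enrich, enrichB, sites, cfg$bands$bands)
    write_table_tsv(bd$table, file.path(cfg$out_dir, "band_difference.tsv"))
    report$stages$bands <- lapply(seq_len(nrow(bd$table)), function(k)
      as.list(bd$table[k, ]))
  })

  report_path <- file.path(cfg$out_dir, "report.yaml")
  writeLines(yaml::as.yaml(report, precision = 15L), report_path)
  say("report written to ", report_path)
  invisible(structure(c(report, list(config = cfg, path = report_path)),
                      class = "run_report"))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$provenance$seed, ", stages: ",
      paste(names(x$stages), collapse = ", "), "\n", sep = "")
  if (!is.null(x$stages$insulation))
    cat(sprintf("  insulation: mean dIS %.3g (p=%s), %.0f%% of sites drop\n",
                x$stages$insulation$mean_dIS,
                format.pval(x$stages$insulation$p, digits = 3),
                100 * x$stages$insulation$frac_negative))
  if (!is.null(x$stages$chip))
    cat(sprintf("  widths: narrow %.3g kb, broad %.3g kb\n",
                x$stages$chip$narrow_fwhm_bp / 1e3,
                x$stages$chip$broad_fwhm_bp / 1e3))
  if (!is.null(x$stages$boundary))
    cat(sprintf("  boundary drop %.3g (p=%s) vs control %.3g\n",
                x$stages$boundary$mean_drop,
                format.pval(x$stages$boundary$p, digits = 3),
                x$stages$boundary$control_mean))
  invisible(x)
}

write_table_tsv <- function(df, path, meta = NULL) {
  hdr <- if (length(meta)) paste0("#", names(meta), "=", meta) else character()
  writeLines(hdr, path)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

write_aggregate_tsv <- function(agg, path) {
  writeLines(c(paste0("#op=", agg$op), paste0("#n=", agg$n),
               paste0("#epsilon=", agg$epsilon),
               paste0("#bin_size=", format(agg$bin_size, scientific = FALSE))),
             path)
  data.table::fwrite(data.table::as.data.table(agg$matrix), path, sep = "\t",
                     col.names = FALSE, append = TRUE)
  invisible(path)
}
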