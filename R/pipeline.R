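#' Analysis configuration with documented defaults
#'
#' One place for every tunable of the NMR and structure pipelines. All
#' defaults are the package's documented conventions; any can be
#' overridden by name. The configuration serializes to a single
#' `key = value` text file ([write_config()]) that is archived with every
#' output bundle, and its hash is embedded in output headers.
#'
#' @param ... overrides by name, e.g. `deadband = 0.5`.
#' @return list of class `dimerlens_config`.
#' @export
dimerlens_config <- function(...) {
  cfg <- list(
    deadband = 0.7,                   # ppm, coil band of the SS index
    csp_thresholds = c(0.25, 0.5, 1.0), # ppm, perturbation tiers
    nitrogen_larmor_mhz = 60.81,      # 15N Larmor on a 600 MHz machine
    noe_min = 0.6,                    # NOE cutoff for protein averages
    trim = 0.1,                       # trimmed-mean fraction for averages
    hbond_dmax = 3.5,                 # A, N...O cutoff
    hbond_angle_min = 120,            # deg, N-H...O when H present
    probe = 1.4,                      # A, SASA probe radius
    n_points = 960,                   # SASA quadrature points per atom
    superpose_elety = "CA",
    superpose_resno = 6:68,           # modelled chemokine core
    register_window = c(5, 15),       # N-terminal interface residues
    contact_dist = 5,                 # A, symmetry-mate contact cutoff
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "dimerlens_config"
  cfg
}

#' Serialize a configuration to a key = value text file
#'
#' @param config a [dimerlens_config()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

# evaluates expr; on error records the message in env$errors[[name]] and
# returns NULL so independent stages keep running
run_stage <- function(name, env, expr) {
  tryCatch(expr, error = function(e) {
    env$errors[[name]] <- conditionMessage(e)
    message("stage '", name, "' failed: ", conditionMessage(e))
    NULL
  })
}

output_header <- function(config, extra = character()) {
  c(paste0("# dimerlens ",
           as.character(utils::packageVersion("dimerlens"))),
    paste0("# config_hash ", config_hash(config)),
    paste0("# ", extra))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the NMR analysis pipeline
#'
#' Chains the shift-based analyses (secondary-shift index, smoothing,
#' secondary-structure calls; perturbation mapping with tiers) and the
#' relaxation analyses (rate fitting, NOE, tumbling time, oligomeric
#' call). Stages run independently: a failing stage is reported by name
#' and the remaining stages still run; missing inputs simply limit the
#' stage set (shift tables alone yield the shift analyses only).
#'
#' @param shifts_a a [shift_table()] or path to one (the state under
#'   study).
#' @param shifts_b optional second state for perturbation mapping.
#' @param r1_decays,r2_decays optional decay tables (`residue_index`,
#'   `delay_s`, `intensity`) or paths readable by [read_decay_table()].
#' @param noe optional data frame `residue_index`, `intensity_sat`,
#'   `intensity_unsat`.
#' @param config a [dimerlens_config()].
#' @param out_dir optional output directory; when given, writes `ss.tsv`,
#'   `csp.tsv`, `rates.tsv`, `tumbling.tsv`, `summary.txt` and
#'   `config.txt`.
#' @return list with `ss`, `csp`, `r1`, `r2`, `noe`, `tumbling`,
#'   `oligomer`, `errors` (named character vector of failed stages).
#' @export
run_nmr_pipeline <- function(shifts_a, shifts_b = NULL,
                             r1_decays = NULL, r2_decays = NULL,
                             noe = NULL, config = dimerlens_config(),
                             out_dir = NULL) {
  if (is.character(shifts_a)) shifts_a <- read_shift_table(shifts_a)
  if (is.character(shifts_b)) shifts_b <- read_shift_table(shifts_b)
  if (is.character(r1_decays)) r1_decays <- read_decay_table(r1_decays)
  if (is.character(r2_decays)) r2_decays <- read_decay_table(r2_decays)
  errors <- list()
  ss <- run_stage("secondary-structure", environment(),
    secondary_structure_profile(shifts_a, deadband = config$deadband))
  csp_prof <- if (!is.null(shifts_b))
    run_stage("csp", environment(),
      tier_csp(csp(shifts_a, shifts_b), config$csp_thresholds)) else NULL
  r1 <- if (!is.null(r1_decays))
    run_stage("r1-fit", environment(), fit_rates(r1_decays)) else NULL
  r2 <- if (!is.null(r2_decays))
    run_stage("r2-fit", environment(), fit_rates(r2_decays)) else NULL
  noe_tab <- if (!is.null(noe))
    run_stage("hetnoe", environment(), {
      nn <- hetnoe(noe$intensity_sat, noe$intensity_unsat)
      data.frame(residue_index = noe$residue_index, noe = nn$noe)
    }) else NULL
  tumbling <- oligomer <- NULL
  if (!is.null(r1) && !is.null(r2)) {
    tumbling <- run_stage("tumbling", environment(), {
      m1 <- average_rates(r1, noe_tab, config$noe_min, config$trim)
      m2 <- average_rates(r2, noe_tab, config$noe_min, config$trim)
      est <- tau_c_from_ratio(m1$mean_rate, m2$mean_rate,
                              config$nitrogen_larmor_mhz)
      list(mean_r1 = m1$mean_rate, mean_r2 = m2$mean_rate, estimate = est)
    })
    if (!is.null(tumbling))
      oligomer <- run_stage("oligomer-call", environment(),
                            classify_oligomer(tumbling$estimate))
  }
  res <- list(ss = ss, csp = csp_prof, r1 = r1, r2 = r2, noe = noe_tab,
              tumbling = tumbling, oligomer = oligomer,
              errors = unlist(errors))
  if (!is.null(out_dir)) write_nmr_bundle(res, config, out_dir)
  res
}

write_nmr_bundle <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.txt"))
  if (!is.null(res$ss))
    write_tsv_with_header(res$ss, file.path(out_dir, "ss.tsv"),
      output_header(config, paste("random-coil:",
        attr(res$ss, "reference_provenance"))))
  if (!is.null(res$csp))
    write_tsv_with_header(res$csp, file.path(out_dir, "csp.tsv"),
      output_header(config, paste("thresholds:",
        paste(config$csp_thresholds, collapse = ","))))
  rates <- NULL
  if (!is.null(res$r1)) {
    r1 <- res$r1; r1$kind <- "R1"; rates <- r1
  }
  if (!is.null(res$r2)) {
    r2 <- res$r2; r2$kind <- "R2"; rates <- rbind(rates, r2)
  }
  if (!is.null(rates))
    write_tsv_with_header(rates, file.path(out_dir, "rates.tsv"),
                          output_header(config, "rates in 1/s"))
  if (!is.null(res$tumbling)) {
    est <- res$tumbling$estimate
    write_tsv_with_header(
      data.frame(mean_r1 = res$tumbling$mean_r1,
                 mean_r2 = res$tumbling$mean_r2,
                 r2_over_r1 = est$r2_over_r1,
                 tau_c_ns = est$tau_c_ns,
                 nu_n_mhz = est$nitrogen_larmor_frequency_mhz),
      file.path(out_dir, "tumbling.tsv"),
      output_header(config, paste("formula:", est$formula_name)))
  }
  summary_lines <- c(
    output_header(config, "NMR pipeline summary"),
    if (!is.null(res$ss))
      sprintf("secondary structure: %d residues, %d helix / %d strand / %d coil",
              nrow(res$ss), sum(res$ss$label == "helix"),
              sum(res$ss$label == "strand"), sum(res$ss$label == "coil")),
    if (!is.null(res$csp))
      sprintf("csp: %d residues, %d above first threshold",
              nrow(res$csp), sum(res$csp$tier > 0)),
    if (!is.null(res$tumbling))
      sprintf("mean R1 = %.2f 1/s, mean R2 = %.2f 1/s, tau_c = %.2f ns",
              res$tumbling$mean_r1, res$tumbling$mean_r2,
              res$tumbling$estimate$tau_c_ns),
    if (!is.null(res$oligomer))
      sprintf("oligomeric state: %s (%s)", res$oligomer$state,
              res$oligomer$basis),
    if (length(res$errors))
      paste("failed stages:", paste(names(res$errors), collapse = ", "))
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Run the structure analysis pipeline
#'
#' For one coordinate file: builds the crystallographic dimer if the
#' model is a single chain with symmetry information, then reports the
#' interchain backbone hydrogen bonds, buried interface area and pairing
#' register. With a second file, additionally superposes the first
#' monomers and reports the integer register shift between the two
#' interfaces.
#'
#' @param model_a a [structure_model()] or path to a PDB/mmCIF file.
#' @param model_b optional second structure for the comparison.
#' @param config a [dimerlens_config()].
#' @param out_dir optional output directory; when given, writes
#'   `interface.tsv`, `interface.txt`, `summary.txt`, `config.txt`.
#' @return list with `dimer_a`, `dimer_b`, `hbonds_a`, `hbonds_b`,
#'   `interface_area_a`, `map_a`, `map_b`, `superposition`,
#'   `register_shift`, `errors`.
#' @export
run_structure_pipeline <- function(model_a, model_b = NULL,
                                   config = dimerlens_config(),
                                   out_dir = NULL) {
  errors <- list()
  as_dimer <- function(m, tag) {
    if (is.character(m)) m <- read_structure(m)
    nch <- length(unique(m$atoms$chain[!m$atoms$is_water]))
    if (nch >= 2) return(m)
    if (is.null(m$cell) || is.null(m$sym_ops))
      stop("structure ", tag,
           ": need symmetry or two chains to analyze a dimer interface")
    build_dimer_from_asu(m, config$contact_dist)
  }
  dimer_a <- run_stage("dimer-a", environment(), as_dimer(model_a, "a"))
  dimer_b <- if (!is.null(model_b))
    run_stage("dimer-b", environment(), as_dimer(model_b, "b")) else NULL
  hb <- function(d) backbone_hbonds(d, config$hbond_dmax,
                                    config$hbond_angle_min)
  hbonds_a <- if (!is.null(dimer_a))
    run_stage("hbonds-a", environment(), hb(dimer_a)) else NULL
  hbonds_b <- if (!is.null(dimer_b))
    run_stage("hbonds-b", environment(), hb(dimer_b)) else NULL
  area_a <- if (!is.null(dimer_a))
    run_stage("interface-area", environment(),
              interface_area(dimer_a, config$probe, config$n_points))
    else NULL
  map_a <- if (!is.null(hbonds_a)) register_map(hbonds_a) else NULL
  map_b <- if (!is.null(hbonds_b)) register_map(hbonds_b) else NULL
  sp <- shift <- NULL
  if (!is.null(dimer_a) && !is.null(dimer_b)) {
    sp <- run_stage("superpose", environment(), {
      mono <- function(d) split_chains(d)[[1]]
      superpose(mono(dimer_a), mono(dimer_b),
                elety = config$superpose_elety,
                resno = config$superpose_resno, on_mismatch = "intersect")
    })
    shift <- run_stage("register-shift", environment(),
      register_shift(map_a, map_b, config$register_window))
  }
  res <- list(dimer_a = dimer_a, dimer_b = dimer_b, hbonds_a = hbonds_a,
              hbonds_b = hbonds_b, interface_area_a = area_a,
              map_a = map_a, map_b = map_b, superposition = sp,
              register_shift = shift, errors = unlist(errors))
  if (!is.null(out_dir)) write_structure_bundle(res, config, out_dir)
  res
}

write_structure_bundle <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.txt"))
  if (!is.null(res$hbonds_a))
    write_tsv_with_header(res$hbonds_a, file.path(out_dir, "interface.tsv"),
      output_header(config, paste("radii:", VDW_PROVENANCE)))
  lines <- c(output_header(config, "structure pipeline summary"))
  if (!is.null(res$interface_area_a))
    lines <- c(lines, sprintf("buried interface area: %.1f A^2",
                              res$interface_area_a))
  if (!is.null(res$map_a) && nrow(res$map_a))
    lines <- c(lines, paste("pairing (a):",
      paste(sprintf("(%d,%d)", res$map_a$res_a, res$map_a$res_b),
            collapse = " ")))
  if (!is.null(res$map_b) && nrow(res$map_b))
    lines <- c(lines, paste("pairing (b):",
      paste(sprintf("(%d,%d)", res$map_b$res_a, res$map_b$res_b),
            collapse = " ")))
  if (!is.null(res$superposition))
    lines <- c(lines, sprintf("monomer superposition RMSD: %.3f A (%s)",
                              res$superposition$rmsd,
                              res$superposition$selection))
  if (!is.null(res$register_shift))
    lines <- c(lines, sprintf("register shift (b vs a): %+d residue(s)",
                              res$register_shift))
  if (length(res$errors))
    lines <- c(lines, paste("failed stages:",
                            paste(names(res$errors), collapse = ", ")))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  writeLines(lines, file.path(out_dir, "interface.txt"))
  invisible(out_dir)
}
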