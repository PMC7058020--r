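#' Bundled presets
#'
#' Tabulates the named parameter presets shipped with the package: the
#' reference membrane ("default", see [default_membrane()]) and the
#' inclusion configurations used throughout the documented scans —
#' lipid stripes of thin/intermediate/thick monolayer thickness and
#' spontaneous curvature 0 or \eqn{\pm 0.25\ \mathrm{nm}^{-1}},
#' hydrophobic peptides with director jumps 0.2/0.4/0.6, and
#' transmembrane shapes (cylinder, hourglass, barrel and their
#' asymmetric halves) with hydrophobic lengths `2*h_s = 2.6`,
#' `h_r + h_s = 3.1` and `2*h_r = 3.6` nm.
#'
#' @param filter optional regular expression on the preset name.
#' @return data frame with columns `name`, `kind`, `description`.
#' @export
list_presets <- function(filter = NULL) {
  tab <- do.call(rbind, lapply(preset_registry(), function(p)
    data.frame(name = p$name, kind = p$kind, description = p$description,
               stringsAsFactors = FALSE)))
  if (!is.null(filter)) tab <- tab[grepl(filter, tab$name), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Retrieve a preset object by name
#'
#' @param name preset name (see [list_presets()]).
#' @return a membrane parameter list or an `inclusion_spec`.
#' @export
get_preset <- function(name) {
  reg <- preset_registry()
  hit <- Filter(function(p) p$name == name, reg)
  if (!length(hit))
    stop("unknown preset '", name, "'; see list_presets()")
  hit[[1]]$build()
}

preset_registry <- function() {
  mem <- default_membrane()
  reg <- list(list(
    name = "default", kind = "membrane",
    description = paste("Lo/Ld pair: B_r = 20, B_s = 10 kBT; h_r = 1.8,",
                        "h_s = 1.3 nm; Kt = 40, Ka = 120 mN/m;",
                        "sigma0 = 0.025 kBT/nm^2; J = 0"),
    build = default_membrane))
  for (h0 in c(1.3, 1.55, 1.8)) {
    for (J0 in c(0, 0.25, -0.25)) {
      nm <- sprintf("stripe_h%.2f_J%+.2f", h0, J0)
      reg <- c(reg, list(list(
        name = nm, kind = "inclusion",
        description = sprintf(
          "lipid stripe: h0 = %.2f nm, J0 = %+.2f 1/nm, B0 = 10 kBT", h0, J0),
        build = local({
          h0c <- h0; J0c <- J0
          function() lipid_stripe(h0 = h0c, J0 = J0c, B0 = 10)
        }))))
    }
  }
  reg <- c(reg, list(list(
    name = "amphipathic", kind = "inclusion",
    description = "shallow amphipathic helix, deltaL = 1.3 nm, geometric director jump",
    build = function() amphipathic_peptide())))
  for (dn in c(0.2, 0.4, 0.6)) {
    for (wh in c("upper", "midplane")) {
      nm <- sprintf("hydrophobic_%s_dn%.1f", wh, dn)
      reg <- c(reg, list(list(
        name = nm, kind = "inclusion",
        description = sprintf("hydrophobic peptide (%s), |dn| = %.1f", wh, dn),
        build = local({
          dnc <- dn; whc <- wh
          function() hydrophobic_peptide(dnc, where = whc)
        }))))
    }
  }
  shapes <- list(cylinder = c(0, 0), hourglass = c(-0.4, -0.4),
                 barrel = c(0.4, 0.4), semi_hourglass = c(-0.4, 0),
                 semi_barrel = c(0.4, 0))
  for (h0 in c(2.6, 3.1, 3.6)) {
    for (sh in names(shapes)) {
      nm <- sprintf("tm_%s_h%.1f", sh, h0)
      dn <- shapes[[sh]]
      reg <- c(reg, list(list(
        name = nm, kind = "inclusion",
        description = sprintf(
          "transmembrane %s: h0 = %.1f nm, dnx_u = %+.1f, dnx_l = %+.1f",
          sh, h0, dn[1], dn[2]),
        build = local({
          h0c <- h0; dnc <- dn
          function() transmembrane_protein(h0 = h0c, dnx_u = dnc[1],
                                           dnx_l = dnc[2])
        }))))
    }
  }
  reg
}

# Build an inclusion_spec from a configuration block (either a preset
# name or family + parameters).
inclusion_from_config <- function(blk) {
  if (is.character(blk)) return(get_preset(blk))
  if (is.null(blk$family)) stop("inclusion block must name a family")
  dl <- blk$deltaL %||% 1.3
  switch(blk$family,
         lipid_stripe = lipid_stripe(h0 = blk$h0, J0 = blk$J0 %||% 0,
                                     B0 = blk$B0 %||% 10, deltaL = dl),
         amphipathic_shallow = amphipathic_peptide(deltaL = dl),
         hydrophobic_deep_upper = hydrophobic_peptide(blk$dn_mag,
                                                      deltaL = dl,
                                                      where = "upper"),
         hydrophobic_midplane = hydrophobic_peptide(blk$dn_mag,
                                                    deltaL = dl,
                                                    where = "midplane"),
         transmembrane = transmembrane_protein(h0 = blk$h0,
                                               dnx_u = blk$dnx_u %||% 0,
                                               dnx_l = blk$dnx_l %||%
                                                 (blk$dnx_u %||% 0),
                                               deltaL = dl),
         stop("unknown inclusion family: ", blk$family))
}

# Resolve a full run configuration (file path or list) into its parts.
resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  mem <- config$membrane %||% "default"
  phases <- if (is.character(mem)) get_preset(mem) else
    read_membrane_config(mem)
  sv <- config$solver %||% list()
  settings <- solver_settings(dx = sv$dx %||% 0.025,
                              half_width = sv$half_width %||% 20,
                              rel_tol = sv$rel_tol %||% 1e-3,
                              max_refinements = sv$max_refinements %||% 6)
  scan <- config$scan
  if (is.null(scan$kind)) stop("scan block must state a kind")
  list(phases = phases, settings = settings, scan = scan,
       inclusion = config$inclusion,
       output_dir = config$output_dir %||% ".",
       config = config)
}

write_scan_outputs <- function(profile, summary, out_dir, stem) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  con <- file(csv, "w")
  writeLines(c("# abscissa: nm; W: kBT/nm",
               sprintf("# kind: %s", profile$kind)), con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  close(con)
  js <- file.path(out_dir, paste0(stem, ".json"))
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(csv = csv, json = js)
}

#' Run a boundary-shift scan from a configuration
#'
#' Computes `W(L)` for the configured membrane, locates the equilibrium
#' shift, and writes the profile (CSV) plus a unit-annotated summary
#' (JSON) into the configured output directory.  The effective
#' configuration is echoed to the console at startup; the whole pipeline
#' is deterministic, so re-running the logged configuration reproduces
#' the outputs exactly.
#'
#' @param config file path or list; needs `scan: {kind: boundary_shift,
#'   L_from, L_to, step}` plus optional `membrane`, `solver`,
#'   `output_dir` blocks.
#' @return (invisibly) the written file paths.
#' @export
cli_boundary_scan <- function(config) {
  rc <- resolve_config(config)
  if (rc$scan$kind != "boundary_shift")
    stop("cli_boundary_scan needs scan kind 'boundary_shift'")
  message("configuration: ",
          jsonlite::toJSON(rc$config, auto_unbox = TRUE))
  Ls <- seq(rc$scan$L_from %||% -6, rc$scan$L_to %||% 6,
            by = rc$scan$step %||% 0.25)
  eq <- find_equilibrium_shift(rc$phases, Ls, rc$settings)
  summary <- list(
    kind = "boundary_shift",
    L0_nm = eq$L0,
    W0_kBT_per_nm = eq$W0,
    line_tension_pN = line_tension_pN(eq$W0),
    schema_version = 1L,
    settings = unclass(rc$settings))
  invisible(write_scan_outputs(eq$profile, summary, rc$output_dir,
                               "boundary_scan"))
}

#' Run an inclusion-position scan from a configuration
#'
#' Computes `W(X0)` for the configured inclusion at fixed boundary shift
#' `L`, analyses plateaus and minima, and writes profile CSV plus summary
#' JSON.
#'
#' @param config file path or list; needs an `inclusion` block and
#'   `scan: {kind: inclusion_position, L, X0_from, X0_to, step}`.
#' @return (invisibly) the written file paths.
#' @export
cli_inclusion_scan <- function(config) {
  rc <- resolve_config(config)
  if (rc$scan$kind != "inclusion_position")
    stop("cli_inclusion_scan needs scan kind 'inclusion_position'")
  if (is.null(rc$inclusion))
    stop("inclusion block is required for an inclusion scan")
  spec <- inclusion_from_config(rc$inclusion)
  message("configuration: ",
          jsonlite::toJSON(rc$config, auto_unbox = TRUE))
  X0s <- seq(rc$scan$X0_from %||% -12, rc$scan$X0_to %||% 12,
             by = rc$scan$step %||% 0.25)
  prof <- inclusion_energy_profile(
    spec, rc$phases, L = rc$scan$L %||% 3, X0_values = X0s,
    settings = rc$settings,
    flatness_tol = rc$scan$flatness_tol %||% 1e-2)
  summary <- list(
    kind = "inclusion_position",
    family = spec$family,
    L_nm = rc$scan$L %||% 3,
    plateau_left_kBT_per_nm = prof$plateau_left,
    plateau_right_kBT_per_nm = prof$plateau_right,
    plateau_difference_kBT_per_nm = prof$plateau_right - prof$plateau_left,
    flat_profile = nrow(prof$minima) == 0,
    minima = prof$minima,
    schema_version = 1L,
    settings = unclass(rc$settings))
  invisible(write_scan_outputs(prof, summary, rc$output_dir,
                               "inclusion_scan"))
}
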