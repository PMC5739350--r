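#' Default model configuration
#'
#' Builds the default parameterization of the three-compartment VEGF
#' transport/kinetics model: compartment geometry, cell populations and
#' their receptor surface densities, binding/coupling/internalization rate
#' constants, secretion rates, inter-compartment transport, anti-VEGF drug
#' kinetics, and tumor growth parameters.
#'
#' Units are fixed throughout the package: time in seconds, volumes in cm^3,
#' concentrations in mol/cm^3 of total compartment volume (blood species per
#' cm^3 plasma), bimolecular rate constants in M^-1 s^-1 for reactions in
#' interstitial fluid or plasma and in (mol/cm^3 tissue)^-1 s^-1 for
#' surface-surface coupling, first-order rates in s^-1, secretion in
#' mol/(cm^3 tissue * s), permeability in cm^3/s per cm^3 tissue, lymph flow
#' in cm^3/s.
#'
#' Each numeric group carries a `provenance` attribute: `"published"` for values
#' printed in the source study, `"default"` for package defaults standing in
#' for unpublished parameter tables.
#'
#' @param ... named overrides merged into the default list (shallow, by
#'   top-level name; use [modify_config()] for deep overrides).
#' @return A list of class `angiofit_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    compartments = list(
      normal = list(volume = 10,   fluid_fraction = 0.10),
      blood  = list(volume = 1.0,  fluid_fraction = 1.0),
      tumor  = list(
        f_vasc       = 0.04,
        f_int0       = 0.50,
        f_int_min    = 0.25,
        lambda       = 1.2,       # 1/cm^3, interstitial-fraction decay
        cell_volume_um3 = 905     # provenance: published value
      )
    ),
    # Cell populations expressing surface receptors.  `cells_per_cm3` is per
    # cm^3 of compartment volume; tumor cells are counted from the geometry
    # (f_cell * V / cell volume) instead.
    populations = list(
      muscle = list(compartment = "normal", cells_per_cm3 = 2e6,
                    receptors = c(VEGFR1 = 10000, VEGFR2 = 2000,
                                  NRP1 = 20000, NRP2 = 0)),
      ec_normal = list(compartment = "normal", cells_per_cm3 = 1e7,
                       receptors = c(VEGFR1 = 10000, VEGFR2 = 10000,
                                     NRP1 = 20000, NRP2 = 0)),
      ec_blood = list(compartment = "blood", cells_per_cm3 = 5e7,
                      receptors = c(VEGFR1 = 10000, VEGFR2 = 10000,
                                    NRP1 = 20000, NRP2 = 0)),
      ec_tumor = list(compartment = "tumor", cells_per_cm3 = 5e7,
                      receptors = c(VEGFR1 = 10000, VEGFR2 = 10000,
                                    NRP1 = 20000, NRP2 = 0)),
      tumor_cell = list(compartment = "tumor", cells_per_cm3 = NA_real_,
                        from_geometry = TRUE,
                        receptors = c(VEGFR1 = 1000, VEGFR2 = 1000,
                                      NRP1 = 20000, NRP2 = 0))
    ),
    # VEGF isoforms.  Heparin-binding isoforms additionally bind NRPs
    # directly and matrix GAG sites.
    ligands = list(
      mVEGF120 = list(origin = "mouse", heparin = FALSE),
      mVEGF164 = list(origin = "mouse", heparin = TRUE),
      hVEGF121 = list(origin = "human", heparin = FALSE),
      hVEGF165 = list(origin = "human", heparin = TRUE)
    ),
    kinetics = list(
      kon_VEGFR1 = 3e7,   koff_VEGFR1 = 1e-4,   # M^-1 s^-1, s^-1
      kon_VEGFR2 = 1e7,   koff_VEGFR2 = 1e-4,
      kon_NRP    = 3.2e6, koff_NRP    = 1e-3,
      kon_GAG    = 4.2e5, koff_GAG    = 1e-2,
      kon_sR1    = 2.2e7, koff_sR1    = 1e-3,
      kon_a2m    = 7e3,   koff_a2m    = 1e-4,
      kc_on      = 1e10,  kc_off      = 1e-2,   # surface coupling
      k_int      = 1e-4                          # internalization, s^-1
    ),
    secretion = list(                            # mol/(cm^3 tissue * s)
      tumor_cell = c(hVEGF121 = 1.3e-19, hVEGF165 = 4.0e-19),
      muscle     = c(mVEGF120 = 4.0e-20, mVEGF164 = 1.2e-19),
      ec_normal  = c(mVEGF120 = 1.0e-20, mVEGF164 = 3.0e-20),
      ec_blood   = c(mVEGF120 = 1.0e-20, mVEGF164 = 3.0e-20),
      ec_tumor   = c(mVEGF120 = 2.0e-20, mVEGF164 = 6.0e-20)
    ),
    soluble = list(
      sR1_secretion = c(normal = 1e-22, blood = 5e-22, tumor = 2e-22),
      sR1_clearance = 1e-5,          # s^-1, plasma
      a2m_conc      = 6e-9,          # mol/cm^3 plasma, held by production
      a2m_turnover  = 1e-5,
      gag_density   = c(normal = 7.5e-13, tumor = 7.5e-13)  # mol/cm^3 tissue
    ),
    clearance = list(ligand = 2e-3),  # plasma VEGF clearance, s^-1
    transport = list(                 # cm^3/s per cm^3 of tissue
      perm_ligand = c(normal = 3e-6, tumor = 1e-5),
      perm_sR1    = c(normal = 1e-7, tumor = 5e-7),
      perm_drug   = c(normal = 4e-7, tumor = 4e-6),
      lymph_flow  = 2e-5              # cm^3/s, normal interstitium -> blood
    ),
    drug = list(
      kon = 5.4e4, koff = 2.19e-5,    # provenance: published value
      k_clear = 5.73e-7,              # provenance: published value
      mw = 1.49e5, body_mass = 0.02,
      affinity_reported_pM = 4456,    # printed value; inconsistent with
                                      # koff/kon (~406 pM); rates are used
      extravasate = TRUE
    ),
    growth = list(
      k0 = 1.2e-6,                    # s^-1
      k1 = 4.0e-7,                    # cm^3/s
      psi = 20,                       # provenance: published value
      Ang0 = NULL,                    # NULL = basal signal computed at V0
      C_Ang = 1,
      variant = "model1",
      V0 = 0.02                       # cm^3
    ),
    rules = list(
      couple_nrp  = TRUE,   # NRPs couple VEGFR1/VEGFR2
      triples     = TRUE,   # VEGF binds VEGFR-NRP complexes
      ang_include_nrp2 = FALSE
    ),
    provenance = list(
      published = c("compartments$tumor$cell_volume_um3", "kinetics (none)",
                "drug$kon", "drug$koff", "drug$k_clear", "growth$psi"),
      note = paste("All other values are package defaults standing in for",
                   "the source study's unpublished supplementary tables.")
    )
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "angiofit_config"
  cfg
}

#' Deep-modify a configuration
#'
#' Recursively merges `overrides` into `config`: list entries are merged by
#' name, leaves are replaced.
#'
#' @param config an `angiofit_config` list.
#' @param overrides a named (nested) list of replacement values.
#' @return the modified configuration.
#' @export
modify_config <- function(config, overrides) {
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(over[[nm]]))) {
        base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  out <- merge_rec(config, overrides)
  class(out) <- "angiofit_config"
  out
}

#' Validate a configuration
#'
#' Checks structural completeness, rate nonnegativity, and geometric
#' consistency (volume fractions in `[0,1]` with `f_vasc + f_int + f_cell = 1`
#' achievable for all V > 0).
#'
#' @param config an `angiofit_config` list.
#' @return `config`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_config <- function(config) {
  need <- c("compartments", "populations", "ligands", "kinetics",
            "secretion", "soluble", "clearance", "transport", "drug",
            "growth", "rules")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("configuration is missing sections: ", paste(miss, collapse = ", "))
  tum <- config$compartments$tumor
  if (tum$f_vasc < 0 || tum$f_vasc > 1 ||
      tum$f_int0 < 0 || tum$f_int0 > 1 ||
      tum$f_int_min < 0 || tum$f_int_min > tum$f_int0)
    stop("tumor volume fractions must satisfy 0 <= f_int_min <= f_int0 <= 1")
  if (tum$f_vasc + tum$f_int0 >= 1)
    stop("f_vasc + f_int0 must be < 1 so the cell fraction is positive")
  rates <- unlist(config$kinetics)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("negative or non-finite rate constant in kinetics: ",
         paste(names(rates)[!is.finite(rates) | rates < 0], collapse = ", "))
  for (p in names(config$populations)) {
    r <- config$populations[[p]]$receptors
    if (any(r < 0)) stop("negative receptor density for population ", p)
    if (!config$populations[[p]]$compartment %in%
        c("normal", "blood", "tumor"))
      stop("population ", p, " assigned to unknown compartment")
  }
  g <- config$growth
  if (g$k0 <= 0 || g$k1 <= 0 || g$psi <= 0 || g$V0 <= 0)
    stop("growth parameters k0, k1, psi, V0 must be positive")
  if (!is.null(g$Ang0) && g$Ang0 <= 0) stop("Ang0 must be positive or NULL")
  if (!g$variant %in% c("model1", "model2"))
    stop("growth variant must be 'model1' or 'model2'")
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param config configuration to write.
#' @return `read_config()` returns a validated `angiofit_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml drops named-vector structure; restore receptor/secretion vectors
  for (p in names(raw$populations))
    raw$populations[[p]]$receptors <- unlist(raw$populations[[p]]$receptors)
  for (p in names(raw$secretion))
    raw$secretion[[p]] <- unlist(raw$secretion[[p]])
  for (nm in c("sR1_secretion", "gag_density"))
    raw$soluble[[nm]] <- unlist(raw$soluble[[nm]])
  for (nm in c("perm_ligand", "perm_sR1", "perm_drug"))
    raw$transport[[nm]] <- unlist(raw$transport[[nm]])
  class(raw) <- "angiofit_config"
  validate_config(raw)
  raw
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  # yaml serializes named atomic vectors as bare sequences; convert them
  # to maps so the names survive the round trip
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namify(unclass(config)), path)
  invisible(path)
}
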