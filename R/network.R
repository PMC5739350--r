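AVOGADRO <- 6.02214076e23

#' Build the three-compartment VEGF reaction network
#'
#' Expands the configuration into an explicit species list and elementary
#' mass-action reaction list for the three compartments (normal tissue,
#' blood, tumor).  The grammar:
#'
#' * every VEGF isoform binds VEGFR1 and VEGFR2;
#' * heparin-binding isoforms (VEGF164/VEGF165) additionally bind NRPs
#'   directly and matrix GAG sites;
#' * NRPs couple to VEGFR1/VEGFR2 on the same membrane, and VEGF binds the
#'   pre-coupled VEGFR-NRP complex (ternary complexes);
#' * soluble VEGFR1 binds all isoforms in all compartments;
#' * alpha-2-macroglobulin sequesters VEGF in plasma;
#' * the anti-VEGF drug binds the human isoforms only, wherever it is
#'   present (blood always; tissue interstitia when extravasation is on);
#' * all cell-surface species are internalized; plasma species are cleared.
#'
#' A receptor with surface density zero generates no species and no
#' reactions.
#'
#' @param config an `angiofit_config`, see [default_config()].
#' @return A list of class `angiofit_network` with elements `species`,
#'   `reactions`, `transport`, `lymph`, `secretion`, `maintenance`,
#'   `ang_species`, and the originating `config`.
#' @export
build_network <- function(config) {
  validate_config(config)
  kin <- config$kinetics
  rules <- config$rules

  sp <- list(); rx <- list()
  add_sp <- function(name, compartment, kind, location,
                     population = NA_character_, constituents = "",
                     ligand = NA_character_) {
    sp[[length(sp) + 1L]] <<- data.frame(
      name = name, compartment = compartment, kind = kind,
      location = location, population = population,
      constituents = constituents, ligand = ligand,
      stringsAsFactors = FALSE)
    name
  }
  add_rxn <- function(r1, r2 = NA_character_, p1 = NA_character_,
                      p2 = NA_character_, k, scale, compartment) {
    if (!is.finite(k) || k < 0)
      stop("negative or non-finite rate constant in reaction ",
           r1, if (!is.na(r2)) paste0(" + ", r2), " -> ",
           if (is.na(p1)) "0" else p1)
    rx[[length(rx) + 1L]] <<- data.frame(
      r1 = r1, r2 = r2, p1 = p1, p2 = p2, k = k, scale = scale,
      compartment = compartment, stringsAsFactors = FALSE)
  }
  rev_rxn <- function(a, b, c, kon, koff, scale, comp) {
    add_rxn(a, b, c, NA, kon, scale, comp)
    add_rxn(c, NA, a, NA_character_, koff, "linear", comp)
    # dissociation has two products
    rx[[length(rx)]]$p2 <<- b
  }

  comps <- c("normal", "blood", "tumor")
  lig_names <- names(config$ligands)
  heparin <- vapply(config$ligands, function(l) isTRUE(l$heparin),
                    logical(1))
  human <- vapply(config$ligands,
                  function(l) identical(l$origin, "human"), logical(1))
  loc_free <- c(normal = "interstitial_fluid", blood = "plasma",
                tumor = "interstitial_fluid")

  # --- free ligands -------------------------------------------------------
  for (cc in comps) for (L in lig_names)
    add_sp(paste(cc, L, sep = "."), cc, "ligand", loc_free[[cc]], ligand = L)

  # --- surface species and reactions per population -----------------------
  kon_R <- c(VEGFR1 = kin$kon_VEGFR1, VEGFR2 = kin$kon_VEGFR2)
  koff_R <- c(VEGFR1 = kin$koff_VEGFR1, VEGFR2 = kin$koff_VEGFR2)
  for (pop in names(config$populations)) {
    pd <- config$populations[[pop]]
    cc <- pd$compartment
    dens <- pd$receptors
    Rs <- intersect(c("VEGFR1", "VEGFR2"), names(dens)[dens > 0])
    Ns <- intersect(c("NRP1", "NRP2"), names(dens)[dens > 0])
    nm <- function(...) paste(cc, pop, paste(..., sep = "_"), sep = ".")
    surface <- character(0)
    reg <- function(parts, lig = NA_character_) {
      s <- paste(cc, pop, paste(parts, collapse = "_"), sep = ".")
      add_sp(s, cc, if (length(parts) > 1) "complex" else "surface_receptor",
             "cell_surface", pop, paste(parts, collapse = "+"), lig)
      surface <<- c(surface, s)
      s
    }
    for (R in c(Rs, Ns)) reg(R)
    pairs <- if (isTRUE(rules$couple_nrp))
      expand.grid(R = Rs, N = Ns, stringsAsFactors = FALSE) else
      data.frame(R = character(0), N = character(0))
    for (i in seq_len(nrow(pairs)))
      reg(c(pairs$R[i], pairs$N[i]))
    for (L in lig_names) {
      for (R in Rs) reg(c(L, R), L)
      if (heparin[[L]]) for (N in Ns) reg(c(L, N), L)
      if (isTRUE(rules$triples))
        for (i in seq_len(nrow(pairs))) reg(c(L, pairs$R[i], pairs$N[i]), L)
    }
    # binding reactions
    free <- function(L) paste(cc, L, sep = ".")
    for (L in lig_names) {
      for (R in Rs)
        rev_rxn(free(L), nm(R), nm(L, R), kon_R[[R]], koff_R[[R]],
                "fluid", cc)
      if (heparin[[L]]) for (N in Ns)
        rev_rxn(free(L), nm(N), nm(L, N), kin$kon_NRP, kin$koff_NRP,
                "fluid", cc)
      if (isTRUE(rules$triples)) for (i in seq_len(nrow(pairs))) {
        R <- pairs$R[i]; N <- pairs$N[i]
        rev_rxn(free(L), nm(R, N), nm(L, R, N), kon_R[[R]], koff_R[[R]],
                "fluid", cc)
        rev_rxn(nm(L, R), nm(N), nm(L, R, N), kin$kc_on, kin$kc_off,
                "surface", cc)
        if (heparin[[L]])
          rev_rxn(nm(L, N), nm(R), nm(L, R, N), kin$kc_on, kin$kc_off,
                  "surface", cc)
      }
    }
    for (i in seq_len(nrow(pairs)))
      rev_rxn(nm(pairs$R[i]), nm(pairs$N[i]), nm(pairs$R[i], pairs$N[i]),
              kin$kc_on, kin$kc_off, "surface", cc)
    # internalization of every surface species
    for (s in surface) add_rxn(s, NA, NA, NA, kin$k_int, "linear", cc)
  }

  # --- soluble VEGFR1 -----------------------------------------------------
  for (cc in comps) {
    s1 <- add_sp(paste(cc, "sR1", sep = "."), cc, "soluble_receptor",
                 loc_free[[cc]])
    for (L in lig_names) {
      cl <- add_sp(paste(cc, "sR1", L, sep = "."), cc, "complex",
                   loc_free[[cc]], constituents = paste("sR1", L, sep = "+"),
                   ligand = L)
      rev_rxn(paste(cc, L, sep = "."), s1, cl, kin$kon_sR1, kin$koff_sR1,
              "fluid", cc)
    }
  }

  # --- matrix GAG sites (tissue interstitia) ------------------------------
  for (cc in c("normal", "tumor")) {
    g <- add_sp(paste(cc, "GAG", sep = "."), cc, "matrix_site",
                "interstitial_fluid")
    for (L in lig_names[heparin]) {
      cl <- add_sp(paste(cc, "GAG", L, sep = "."), cc, "complex",
                   "interstitial_fluid",
                   constituents = paste("GAG", L, sep = "+"), ligand = L)
      rev_rxn(paste(cc, L, sep = "."), g, cl, kin$kon_GAG, kin$koff_GAG,
              "fluid", cc)
    }
  }

  # --- alpha-2-macroglobulin (plasma) -------------------------------------
  a2m <- add_sp("blood.a2m", "blood", "inhibitor", "plasma")
  for (L in lig_names) {
    cl <- add_sp(paste("blood.a2m", L, sep = "."), "blood", "complex",
                 "plasma", constituents = paste("a2m", L, sep = "+"),
                 ligand = L)
    rev_rxn(paste("blood", L, sep = "."), a2m, cl, kin$kon_a2m,
            kin$koff_a2m, "fluid", "blood")
  }

  # --- anti-VEGF drug -----------------------------------------------------
  drug_comps <- if (isTRUE(config$drug$extravasate)) comps else "blood"
  for (cc in drug_comps) {
    d <- add_sp(paste(cc, "drug", sep = "."), cc, "drug", loc_free[[cc]])
    for (L in lig_names[human]) {
      cl <- add_sp(paste(cc, "drug", L, sep = "."), cc, "complex",
                   loc_free[[cc]], constituents = paste("drug", L, sep = "+"),
                   ligand = L)
      rev_rxn(paste(cc, L, sep = "."), d, cl, config$drug$kon,
              config$drug$koff, "fluid", cc)
    }
  }

  # --- plasma clearance ---------------------------------------------------
  for (L in lig_names)
    add_rxn(paste("blood", L, sep = "."), NA, NA, NA,
            config$clearance$ligand, "linear", "blood")
  add_rxn("blood.sR1", NA, NA, NA, config$soluble$sR1_clearance,
          "linear", "blood")
  for (L in lig_names)
    add_rxn(paste("blood.sR1", L, sep = "."), NA, NA, NA,
            config$soluble$sR1_clearance, "linear", "blood")
  add_rxn("blood.a2m", NA, NA, NA, config$soluble$a2m_turnover,
          "linear", "blood")
  for (L in lig_names)
    add_rxn(paste("blood.a2m", L, sep = "."), NA, NA, NA,
            config$soluble$a2m_turnover, "linear", "blood")
  # cleared drug is routed into a bookkeeping pool so the drug mass
  # balance (infused = free + bound + cleared) closes exactly
  clr <- add_sp("blood.drug_cleared", "blood", "drug", "plasma")
  add_rxn("blood.drug", NA, clr, NA, config$drug$k_clear, "linear", "blood")
  for (L in lig_names[human])
    add_rxn(paste("blood.drug", L, sep = "."), NA, clr, NA,
            config$drug$k_clear, "linear", "blood")

  species <- do.call(rbind, sp)
  if (anyDuplicated(species$name))
    stop("duplicate species generated: ",
         species$name[duplicated(species$name)][1])
  reactions <- do.call(rbind, rx)
  # integrity: every referenced species exists
  refs <- unique(stats::na.omit(c(reactions$r1, reactions$r2,
                                  reactions$p1, reactions$p2)))
  bad <- setdiff(refs, species$name)
  if (length(bad))
    stop("reaction references unknown species: ",
         paste(bad, collapse = ", "))

  # --- transport edges (blood <-> tissue permeability) --------------------
  tr <- list()
  add_tr <- function(blood_sp, tissue_sp, tissue_comp, perm) {
    tr[[length(tr) + 1L]] <<- data.frame(
      blood = blood_sp, tissue = tissue_sp, compartment = tissue_comp,
      perm_per_cm3 = perm, stringsAsFactors = FALSE)
  }
  for (cc in c("normal", "tumor")) {
    for (L in lig_names)
      add_tr(paste("blood", L, sep = "."), paste(cc, L, sep = "."), cc,
             config$transport$perm_ligand[[cc]])
    add_tr("blood.sR1", paste(cc, "sR1", sep = "."), cc,
           config$transport$perm_sR1[[cc]])
    if (isTRUE(config$drug$extravasate)) {
      add_tr("blood.drug", paste(cc, "drug", sep = "."), cc,
             config$transport$perm_drug[[cc]])
      # drug-VEGF complexes permeate like the free antibody (same size),
      # so tissue-captured VEGF can reach plasma and be cleared
      for (L in lig_names[human])
        add_tr(paste("blood.drug", L, sep = "."),
               paste(cc, "drug", L, sep = "."), cc,
               config$transport$perm_drug[[cc]])
    }
  }
  transport <- do.call(rbind, tr)

  # --- lymph (normal interstitium -> blood), mobile species only ----------
  mobile <- species[species$compartment == "normal" &
                    species$location == "interstitial_fluid" &
                    species$kind != "matrix_site" &
                    !grepl("^normal\\.GAG", species$name), "name"]
  blood_partner <- sub("^normal\\.", "blood.", mobile)
  keep <- blood_partner %in% species$name
  lymph <- data.frame(from = mobile[keep], to = blood_partner[keep],
                      stringsAsFactors = FALSE)

  # --- secretion ----------------------------------------------------------
  sec <- list()
  for (pop in names(config$secretion)) {
    cc <- config$populations[[pop]]$compartment
    q <- config$secretion[[pop]]
    for (L in names(q))
      sec[[length(sec) + 1L]] <- data.frame(
        species = paste(cc, L, sep = "."), rate = q[[L]],
        stringsAsFactors = FALSE)
  }
  for (cc in comps)
    sec[[length(sec) + 1L]] <- data.frame(
      species = paste(cc, "sR1", sep = "."),
      rate = config$soluble$sR1_secretion[[cc]], stringsAsFactors = FALSE)
  sec[[length(sec) + 1L]] <- data.frame(
    species = "blood.a2m",
    rate = config$soluble$a2m_conc * config$soluble$a2m_turnover,
    stringsAsFactors = FALSE)
  secretion <- do.call(rbind, sec)
  secretion <- stats::aggregate(rate ~ species, secretion, sum)

  # --- maintained surface/matrix densities --------------------------------
  mt <- list()
  for (pop in names(config$populations)) {
    pd <- config$populations[[pop]]
    cc <- pd$compartment
    dens <- pd$receptors
    for (R in names(dens)[dens > 0]) {
      s <- paste(cc, pop, R, sep = ".")
      if (!s %in% species$name) next
      rho <- if (isTRUE(pd$from_geometry)) dens[[R]] / AVOGADRO else
        pd$cells_per_cm3 * dens[[R]] / AVOGADRO
      mt[[length(mt) + 1L]] <- data.frame(
        species = s, compartment = cc,
        mode = if (isTRUE(pd$from_geometry)) "tumor_cell" else "constant",
        rho = rho, k_maint = kin$k_int, stringsAsFactors = FALSE)
    }
  }
  for (cc in c("normal", "tumor"))
    mt[[length(mt) + 1L]] <- data.frame(
      species = paste(cc, "GAG", sep = "."), compartment = cc,
      mode = "constant", rho = config$soluble$gag_density[[cc]],
      k_maint = 0, stringsAsFactors = FALSE)
  maintenance <- do.call(rbind, mt)

  # --- pro-angiogenic complex inventory -----------------------------------
  ang <- angiogenic_species(species, config)

  net <- structure(list(species = species, reactions = reactions,
                        transport = transport, lymph = lymph,
                        secretion = secretion, maintenance = maintenance,
                        ang_species = ang, config = config),
                   class = "angiofit_network")
  # pre-pack the flat representation used by the compiled RHS so repeated
  # simulations (fitting, sensitivity analysis) skip the translation cost
  net$packed <- make_packed(net)
  net
}

#' Identify pro-angiogenic complexes
#'
#' The angiogenic signal sums the tumor-endothelial-cell complexes that
#' contain one VEGF isoform (mouse or human) bound to VEGFR1 or VEGFR2,
#' with or without NRP1.  Free receptors, VEGF bound only to NRPs, GAG- or
#' soluble-receptor-bound VEGF, and drug complexes are excluded.  Whether
#' NRP2-containing ternary complexes count is configurable
#' (`rules$ang_include_nrp2`, default off).
#'
#' @param species species table from [build_network()].
#' @param config the originating configuration.
#' @return character vector of qualifying species names.
#' @keywords internal
angiogenic_species <- function(species, config) {
  ec <- species[species$population %in% "ec_tumor" &
                species$kind == "complex", , drop = FALSE]
  if (!nrow(ec)) return(character(0))
  parts <- strsplit(ec$constituents, "+", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    has_lig <- any(p %in% names(config$ligands))
    has_r <- any(p %in% c("VEGFR1", "VEGFR2"))
    has_n2 <- "NRP2" %in% p
    has_lig && has_r &&
      (isTRUE(config$rules$ang_include_nrp2) || !has_n2)
  }, logical(1))
  ec$name[ok]
}

#' @export
print.angiofit_network <- function(x, ...) {
  cat("angiofit reaction network\n")
  cat("  species:  ", nrow(x$species), "in",
      length(unique(x$species$compartment)), "compartments\n")
  cat("  reactions:", nrow(x$reactions), "\n")
  cat("  transport edges:", nrow(x$transport),
      "| lymph edges:", nrow(x$lymph), "\n")
  cat("  pro-angiogenic complexes:", length(x$ang_species), "\n")
  invisible(x)
}
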