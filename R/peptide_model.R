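#' @title Side-chain ligand kinds and their hydrogen-bonding patterns
#' @description The closed set of side-chain H-bonding ligands the model
#'   polypeptides can carry. `"triazole"` is the neutral 1,2,3-triazole
#'   (donor C5-H, acceptor N3: binary pattern); `"triazolium"` is its
#'   N3-protonated cation (donors N3-H and C5-H, no acceptor: unitary
#'   pattern).
#' @export
LIGAND_KINDS <- c("amide", "ester", "triazole", "triazolium",
                  "trimethylammonium", "water")

ATOM_MASS <- c(N = 14.007, C = 12.011, O = 15.999, H = 1.008)

check_ligand <- function(ligand) {
  if (!is.character(ligand) || length(ligand) != 1L || !ligand %in% LIGAND_KINDS)
    stop("unknown ligand kind: ", paste(ligand, collapse = ","),
         " (must be one of ", paste(LIGAND_KINDS, collapse = ", "), ")")
  ligand
}

#' Hydrogen-bonding role of a side-chain ligand
#'
#' Classifies a functional group by its donor/acceptor census into the
#' binary (BHB: at least one donor and one acceptor) or unitary (UHB:
#' donors only, or acceptors only) hydrogen-bonding pattern. The amide and
#' the neutral triazole are BHB; the ester (carbonyl acceptor only) is
#' UHB-acceptor; the triazolium, having lost its N3 acceptor to protonation
#' and gained an N3-H donor, is UHB-donor with two donors.
#'
#' @param ligand one of [LIGAND_KINDS].
#' @return an object of class `HBondRole`: list with `donors`, `acceptors`
#'   (site counts) and `pattern` (`"BHB"`, `"UHB_donor"`, `"UHB_acceptor"`
#'   or `"none"`).
#' @examples
#' hbond_pattern("triazole")$pattern    # "BHB"
#' hbond_pattern("triazolium")$donors   # 2
#' @export
hbond_pattern <- function(ligand) {
  check_ligand(ligand)
  tab <- list(
    amide              = c(donors = 1L, acceptors = 1L),
    ester              = c(donors = 0L, acceptors = 1L),
    triazole           = c(donors = 1L, acceptors = 1L),
    triazolium         = c(donors = 2L, acceptors = 0L),
    trimethylammonium  = c(donors = 0L, acceptors = 0L),
    water              = c(donors = 2L, acceptors = 1L)
  )[[ligand]]
  d <- tab[["donors"]]; a <- tab[["acceptors"]]
  pattern <- if (d >= 1L && a >= 1L) "BHB"
  else if (d >= 1L) "UHB_donor"
  else if (a >= 1L) "UHB_acceptor"
  else "none"
  structure(list(donors = d, acceptors = a, pattern = pattern),
            class = "HBondRole")
}

# side-chain atom records for one residue; `protonated` only meaningful for
# the triazole/triazolium pair
sidechain_atoms <- function(ligand, protonated) {
  site <- switch(ligand,
    amide      = data.frame(name = c("OS", "NS", "HS"),
                            element = c("O", "N", "H"),
                            donor = c(FALSE, TRUE, FALSE),
                            acceptor = c(TRUE, FALSE, FALSE),
                            h_parent = c(NA, NA, "NS")),
    ester      = data.frame(name = "OS", element = "O", donor = FALSE,
                            acceptor = TRUE, h_parent = NA),
    triazole   = if (protonated)
      data.frame(name = c("N3", "H3", "C5", "H5"),
                 element = c("N", "H", "C", "H"),
                 donor = c(TRUE, FALSE, TRUE, FALSE),
                 acceptor = FALSE,
                 h_parent = c(NA, "N3", NA, "C5"))
    else
      data.frame(name = c("N3", "C5", "H5"),
                 element = c("N", "C", "H"),
                 donor = c(FALSE, TRUE, FALSE),
                 acceptor = c(TRUE, FALSE, FALSE),
                 h_parent = c(NA, NA, "C5")),
    trimethylammonium = NULL)
  rbind(
    data.frame(name = "CB", element = "C", donor = FALSE, acceptor = FALSE,
               h_parent = NA),
    site,
    data.frame(name = "NT", element = "N", donor = FALSE, acceptor = FALSE,
               h_parent = NA)
  )
}

#' Build the topology of a model polypeptide
#'
#' Constructs a coarse residue/atom topology for an `n_residues`-mer whose
#' every side-chain carries the given H-bonding ligand plus a terminal
#' quaternary trimethylammonium (+1 e each, providing pH-independent
#' solubility). Backbone atoms are the amide N, H, C-alpha, carbonyl C and O
#' of each residue; side-chains are represented coarsely by a linker
#' pseudo-atom (CB), the ligand donor/acceptor sites, and the terminal
#' ammonium nitrogen (NT). Termini are zwitterionic (+1/-1, cancelling in
#' the net charge).
#'
#' Requesting `protonated = TRUE` for a triazole chain protonates every N3,
#' turning each ligand into a triazolium and adding +1 e per residue; use
#' [set_protonation()] for mixed-state chains.
#'
#' @param n_residues chain length (>= 2).
#' @param ligand side-chain ligand kind, see [LIGAND_KINDS].
#' @param protonated logical; protonate every protonatable site.
#' @return a `PeptideModel`: list with `n_residues`, `ligand` (per-residue,
#'   reflecting protonation), `protonation` (logical per residue), `atoms`
#'   (data frame: `atom_id`, `residue`, `name`, `element`, `mass`, `region`,
#'   `donor`, `acceptor`, `h_of`), `zwitterion = TRUE`.
#' @examples
#' m <- build_topology(10, "triazole", protonated = FALSE)
#' net_formal_charge(m)  # +10, one ammonium per side-chain
#' @export
build_topology <- function(n_residues, ligand, protonated = FALSE) {
  check_ligand(ligand)
  if (ligand == "water")
    stop("'water' is a solvent species, not a side-chain ligand")
  if (!is.numeric(n_residues) || n_residues < 2)
    stop("n_residues must be >= 2")
  n_residues <- as.integer(n_residues)
  if (ligand == "triazolium") { ligand <- "triazole"; protonated <- TRUE }
  if (protonated && ligand != "triazole")
    stop("ligand '", ligand, "' has no protonatable site")

  model <- structure(
    list(n_residues = n_residues, base_ligand = ligand,
         protonation = rep(isTRUE(protonated), n_residues),
         zwitterion = TRUE),
    class = "PeptideModel")
  rebuild_atoms(model)
}

# regenerate the atom table from the protonation vector
rebuild_atoms <- function(model) {
  backbone <- data.frame(name = c("N", "H", "CA", "C", "O"),
                         element = c("N", "H", "C", "C", "O"),
                         donor = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                         acceptor = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                         h_parent = c(NA, "N", NA, NA, NA))
  rows <- lapply(seq_len(model$n_residues), function(i) {
    sc <- sidechain_atoms(model$base_ligand, model$protonation[i])
    at <- rbind(cbind(backbone, region = "backbone"),
                cbind(sc, region = "sidechain"))
    at$residue <- i
    at
  })
  atoms <- do.call(rbind, rows)
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms$mass <- ATOM_MASS[atoms$element]
  # resolve hydrogen -> parent donor heavy atom within the same residue
  atoms$h_of <- NA_integer_
  hy <- which(!is.na(atoms$h_parent))
  for (k in hy) {
    atoms$h_of[k] <- atoms$atom_id[atoms$residue == atoms$residue[k] &
                                   atoms$name == atoms$h_parent[k]]
  }
  atoms$h_parent <- NULL
  rownames(atoms) <- NULL
  model$atoms <- atoms[, c("atom_id", "residue", "name", "element", "mass",
                           "region", "donor", "acceptor", "h_of")]
  model$ligand <- ifelse(model$protonation & model$base_ligand == "triazole",
                         "triazolium", model$base_ligand)
  model
}

#' Set per-residue protonation states
#'
#' @param model a `PeptideModel` with triazole/triazolium side-chains.
#' @param flags logical vector of length `n_residues`.
#' @return the updated model (atom table rebuilt).
#' @export
set_protonation <- function(model, flags) {
  stopifnot(inherits(model, "PeptideModel"))
  if (model$base_ligand != "triazole")
    stop("ligand '", model$base_ligand, "' has no protonatable site")
  if (length(flags) != model$n_residues || !is.logical(flags))
    stop("flags must be a logical vector of length n_residues")
  model$protonation <- flags
  rebuild_atoms(model)
}

#' Net formal charge of a model polypeptide
#'
#' Sum of side-chain formal charges in elementary units: +1 per terminal
#' trimethylammonium (one per residue) and +1 per protonated triazolium N3.
#' The zwitterionic termini carry +1/-1 that cancel and never enter the
#' total.
#'
#' @param model a `PeptideModel`.
#' @return integer charge (e).
#' @examples
#' net_formal_charge(build_topology(10, "triazole", FALSE))  # 10
#' net_formal_charge(build_topology(10, "triazole", TRUE))   # 20
#' @export
net_formal_charge <- function(model) {
  stopifnot(inherits(model, "PeptideModel"))
  ammonium <- model$n_residues            # +1 per side-chain NT
  extra <- if (model$base_ligand == "triazole") sum(model$protonation) else 0L
  as.integer(ammonium + extra)
}

#' Per-residue formal charge ledger
#'
#' @param model a `PeptideModel`.
#' @return integer vector of per-residue charges (e); `sum()` of it equals
#'   [net_formal_charge()].
#' @export
charge_ledger <- function(model) {
  stopifnot(inherits(model, "PeptideModel"))
  base <- rep(1L, model$n_residues)
  if (model$base_ligand == "triazole") base + as.integer(model$protonation)
  else base
}

#' @export
print.PeptideModel <- function(x, ...) {
  cat(sprintf("PeptideModel: %d-mer, ligand %s (%d/%d protonated), net charge %+d e\n",
              x$n_residues, x$base_ligand, sum(x$protonation), x$n_residues,
              net_formal_charge(x)))
  cat(sprintf("  %d atoms (%d backbone, %d side-chain)\n", nrow(x$atoms),
              sum(x$atoms$region == "backbone"),
              sum(x$atoms$region == "sidechain")))
  invisible(x)
}
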