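#' Read an atomic model from PDB or mmCIF
#'
#' Builds a chain/residue/atom table from a coordinate file. Alternate
#' locations are resolved to the highest-occupancy conformer; hydrogens and
#' HETATM records are kept but play no role in Calpha mapping.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param model_id Identifier for the model; defaults to the file stem.
#' @param role Declared role in dynamics classification: `"primary"` (the
#'   reference conformation, e.g. an open-head S1 model) or `"alternate"`
#'   (an alternate conformation such as a bent-lever blocked-head
#'   geometry).
#' @return An `xlms_model`: list with `model_id`, `role`, `atoms`
#'   (`data.frame`: `chain`, `resno`, `resid`, `elety`, `elesy`, `x`, `y`,
#'   `z`), plus empty `chain_map`/`offset` to be set by
#'   [set_model_mapping()].
#' @export
read_structure <- function(path, model_id = NULL,
                           role = c("primary", "alternate")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
  } else {
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  }
  atoms <- pdb$atom
  if (!nrow(atoms)) stop("no atoms parsed from ", path)
  # resolve altlocs: keep the highest-occupancy conformer per atom site
  alt <- atoms$alt
  if (is.null(alt)) alt <- rep(NA_character_, nrow(atoms))
  has_alt <- !is.na(alt) & alt != "" & alt != " "
  if (any(has_alt)) {
    site <- paste(atoms$chain, atoms$resno, atoms$elety, sep = "\r")
    occ <- atoms$o
    occ[is.na(occ)] <- 1
    keep <- rep(TRUE, nrow(atoms))
    for (s in unique(site[has_alt])) {
      idx <- which(site == s)
      if (length(idx) > 1L) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  atoms <- data.frame(
    chain = as.character(atoms$chain),
    resno = as.integer(atoms$resno),
    resid = as.character(atoms$resid),
    elety = as.character(atoms$elety),
    elesy = if (!is.null(atoms$elesy)) as.character(atoms$elesy) else
      substr(gsub("[0-9']", "", atoms$elety), 1, 1),
    x = atoms$x, y = atoms$y, z = atoms$z,
    stringsAsFactors = FALSE
  )
  structure(list(
    model_id = model_id %||% tools::file_path_sans_ext(basename(path)),
    role = role,
    atoms = atoms,
    chain_map = character(0),
    offset = integer(0)
  ), class = "xlms_model")
}

#' Build an `xlms_model` from an in-memory atom table
#'
#' Used by the synthetic generators; same contract as [read_structure()].
#'
#' @param atoms `data.frame` with `chain`, `resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`.
#' @param model_id Identifier.
#' @param role `"primary"` or `"alternate"`.
#' @return An `xlms_model`.
#' @export
as_xlms_model <- function(atoms, model_id, role = "primary") {
  stopifnot(all(c("chain", "resno", "elety", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  if (is.null(atoms$elesy)) {
    atoms$elesy <- substr(gsub("[0-9']", "", atoms$elety), 1, 1)
  }
  structure(list(model_id = model_id, role = match.arg(role, c("primary", "alternate")),
                 atoms = atoms, chain_map = character(0), offset = integer(0)),
            class = "xlms_model")
}

#' Declare how construct residue numbering maps onto a model
#'
#' Cross-link tables live in construct coordinates (1-based in the supplied
#' FASTA, initiator methionine included); deposited models may use mature-
#' protein numbering and separate chains. The mapping is one chain id and
#' one integer offset per protein: model residue number =
#' construct index + offset.
#'
#' @param model `xlms_model`.
#' @param chain_map Named character vector, protein_id -> chain id.
#' @param offset Named integer vector, protein_id -> numbering offset
#'   (default 0 for proteins not named).
#' @return The model with the mapping attached.
#' @export
set_model_mapping <- function(model, chain_map, offset = integer(0)) {
  stopifnot(inherits(model, "xlms_model"), !is.null(names(chain_map)))
  missing_chain <- setdiff(unname(chain_map), unique(model$atoms$chain))
  if (length(missing_chain)) {
    stop("chain(s) named in chain_map absent from model '", model$model_id,
         "': ", paste(missing_chain, collapse = ", "))
  }
  model$chain_map <- chain_map
  model$offset <- offset
  model
}

# Translate (protein_id, construct index) to (chain, model resno);
# chain NA when the protein is not mapped into this model.
resolve_model_residue <- function(model, protein, site) {
  chain <- model$chain_map[protein]
  if (is.na(chain)) return(list(chain = NA_character_, resno = NA_integer_))
  off <- model$offset[protein]
  if (is.na(off)) off <- 0L
  list(chain = unname(chain), resno = as.integer(site + off))
}

ca_coords <- function(model, chain, resno) {
  a <- model$atoms
  hit <- a$chain == chain & a$resno == resno & a$elety == "CA"
  if (!any(hit)) return(NULL)
  as.numeric(a[which(hit)[1], c("x", "y", "z")])
}

#' Calpha-Calpha Euclidean distance between two residues of a model
#'
#' @param model `xlms_model`.
#' @param chain_a,resno_a,chain_b,resno_b Model-space residue addresses.
#' @return Distance in Angstrom, or `NA` if either Calpha is absent.
#' @export
ca_distance <- function(model, chain_a, resno_a, chain_b, resno_b) {
  p <- ca_coords(model, chain_a, resno_a)
  q <- ca_coords(model, chain_b, resno_b)
  if (is.null(p) || is.null(q)) return(NA_real_)
  sqrt(sum((p - q)^2))
}

#' Annotate cross-links with Calpha-Calpha distances in atomic models
#'
#' For every (cross-link, model) pair, the Calpha-Calpha distance is
#' measured and compared against the cross-linker reach criterion
#' (`within_reach` is `d_ca <= reach`, inclusive; 30 Angstrom is the
#' accepted DSBU limit). Monolinks are skipped (no residue pair). A link
#' whose sites carry ambiguous candidate residues is annotated with the
#' minimum distance over candidates: reachability only requires one
#' candidate in range. Links spanning proteins absent from a model, or
#' residues outside its modeled range, get `mapped = FALSE` rather than an
#' error.
#'
#' @param links `data.frame` with `link` keys (e.g. the `links` slot of an
#'   `xlms_quant`, or an `xlms_diff`); optional column `candidates_a` /
#'   `candidates_b` (semicolon-separated alternative construct indices).
#' @param models List of `xlms_model`s with mappings set.
#' @param reach Reach threshold in Angstrom (default 30, inclusive).
#' @return `data.frame` (class `xlms_annotation`): `link`, `model_id`,
#'   `role`, `d_ca`, `mapped`, `within_reach`.
#' @export
annotate_link_distances <- function(links, models, reach = 30.0) {
  if (inherits(models, "xlms_model")) models <- list(models)
  keys <- unique(links$link)
  cand_a <- if ("candidates_a" %in% names(links)) {
    setNames(links$candidates_a, links$link)
  } else NULL
  cand_b <- if ("candidates_b" %in% names(links)) {
    setNames(links$candidates_b, links$link)
  } else NULL

  rows <- list()
  for (key in keys) {
    sites <- parse_link_key(key)
    if (nrow(sites) != 2L) next  # monolink
    sa <- sites$site[1]
    sb <- sites$site[2]
    alt_a <- union(sa, parse_candidates(if (is.null(cand_a)) NA else cand_a[[key]]))
    alt_b <- union(sb, parse_candidates(if (is.null(cand_b)) NA else cand_b[[key]]))
    for (model in models) {
      d_best <- NA_real_
      for (ra in alt_a) for (rb in alt_b) {
        a <- resolve_model_residue(model, sites$protein[1], ra)
        b <- resolve_model_residue(model, sites$protein[2], rb)
        if (is.na(a$chain) || is.na(b$chain)) next
        d <- ca_distance(model, a$chain, a$resno, b$chain, b$resno)
        if (!is.na(d) && (is.na(d_best) || d < d_best)) d_best <- d
      }
      rows[[length(rows) + 1L]] <- data.frame(
        link = key, model_id = model$model_id, role = model$role,
        d_ca = d_best, mapped = !is.na(d_best),
        within_reach = if (is.na(d_best)) NA else d_best <= reach,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(link = character(0), model_id = character(0),
               role = character(0), d_ca = numeric(0), mapped = logical(0),
               within_reach = logical(0))
  }
  structure(out, class = c("xlms_annotation", "data.frame"), reach = reach)
}

DYNAMICS_CATEGORIES <- c("stabilized_state", "alternate_state_sampling",
                         "increased_dynamics", "lost_exploratory",
                         "redistribution", "no_change", "unannotated")

#' Classify significant cross-links into conformational-dynamics categories
#'
#' Combines the differential call with the reach pattern across models.
#' For a significantly increased link: within reach in every mapped primary
#' model means the modeled state is sampled more (`stabilized_state`);
#' beyond reach in the primaries but within reach in a declared
#' alternate-conformation model means that alternate state is being sampled
#' (`alternate_state_sampling`); beyond reach everywhere means more
#' excursions from all modeled states (`increased_dynamics`). For a
#' significant decrease: beyond reach in the primaries is a lost
#' exploratory contact (`lost_exploratory`); within reach is signal
#' redistribution away from the modeled state (`redistribution`).
#' Non-significant links are `no_change`; links unmapped in every model
#' are `unannotated`.
#'
#' @param diff `xlms_diff` from [differential_test()].
#' @param annotations `xlms_annotation` from [annotate_link_distances()].
#' @return `data.frame` (class `xlms_dynamics`): `link`, `category`,
#'   `direction`, `fold_change`, `p_value`, plus per-role reach summaries
#'   (`reach_primary`, `reach_alternate`: "within", "beyond", or `NA` when
#'   unmapped) and `supporting_models`.
#' @export
classify_dynamics <- function(diff, annotations) {
  res <- lapply(seq_len(nrow(diff)), function(i) {
    key <- diff$link[i]
    ann <- annotations[annotations$link == key & annotations$mapped, , drop = FALSE]
    prim <- ann[ann$role == "primary", , drop = FALSE]
    altr <- ann[ann$role == "alternate", , drop = FALSE]
    reach_primary <- if (nrow(prim) == 0) NA_character_
      else if (all(prim$within_reach)) "within"
      else if (all(!prim$within_reach)) "beyond" else "mixed"
    reach_alternate <- if (nrow(altr) == 0) NA_character_
      else if (any(altr$within_reach)) "within" else "beyond"

    category <- if (!diff$significant[i]) {
      "no_change"
    } else if (nrow(ann) == 0) {
      "unannotated"
    } else if (diff$direction[i] == "increase") {
      if (!is.na(reach_primary) && reach_primary == "within") {
        "stabilized_state"
      } else if (!is.na(reach_alternate) && reach_alternate == "within") {
        "alternate_state_sampling"
      } else {
        "increased_dynamics"
      }
    } else {
      if (!is.na(reach_primary) && reach_primary == "beyond") {
        "lost_exploratory"
      } else {
        "redistribution"
      }
    }
    data.frame(link = key, category = category,
               direction = diff$direction[i],
               fold_change = diff$fold_change[i],
               p_value = diff$p_value[i],
               reach_primary = reach_primary,
               reach_alternate = reach_alternate,
               supporting_models = paste(ann$model_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("xlms_dynamics", "data.frame"))
}
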