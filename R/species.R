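#' Lipid class codes understood by the package
#'
#' The closed set of head-group codes covering the glycerophospholipids,
#' neutral lipids and sphingomyelin handled by the pipeline. Unknown codes are
#' rejected loudly rather than dropped, because silently dropping species would
#' bias mol\% denominators.
#'
#' @return Character vector of class codes.
#' @export
#' @examples
#' lipid_classes()
lipid_classes <- function() {
  c("PC", "PE", "PS", "PI", "PA", "PG", "DAG", "TAG", "CE", "LPC", "SM")
}

# number of acyl chains carried by each class (SM's sphingoid base is treated
# as a single sum-composition chain; finer sphingolipid grammar is out of scope)
.n_chains <- c(
  PC = 2L, PE = 2L, PS = 2L, PI = 2L, PA = 2L, PG = 2L,
  DAG = 2L, TAG = 3L, CE = 1L, LPC = 1L, SM = 1L
)

#' Parse shorthand lipid species names
#'
#' Accepts the sum-composition forms `"PE 32:1"` / `"PE(32:1)"` and the
#' per-chain form `"PC(C16:0-d31/C18:1)"` (the `C` prefix is optional).
#' An isotope suffix such as `-d31` marks a deuterated internal standard;
#' species carrying one anywhere are flagged `is_internal_standard` and are
#' excluded from all biology-facing compositions downstream.
#'
#' @param x Character vector of species names.
#' @return A tibble with one row per input: `species` (canonical name),
#'   `lipid_class`, `total_carbons`, `total_double_bonds`, `chains` (list
#'   column of tibbles with `carbons`, `double_bonds`, `label`, or `NULL` for
#'   sum compositions), `isotope_label`, `is_internal_standard`.
#' @export
#' @examples
#' parse_species(c("PE 32:1", "PC(C16:0-d31/C18:1)"))
parse_species <- function(x) {
  stopifnot(is.character(x))
  m <- stringr::str_match(
    stringr::str_trim(x),
    "^([A-Za-z]{1,4})\\s*(?:\\(\\s*([^()]+?)\\s*\\)|\\s+(\\S.*))$"
  )
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(sprintf("Cannot parse lipid species name: '%s'", x[which(bad)[1]]))
  }
  cls <- toupper(m[, 2])
  unknown <- !(cls %in% lipid_classes())
  if (any(unknown)) {
    abort(sprintf(
      "Unknown lipid class code '%s' in species '%s'",
      cls[which(unknown)[1]], x[which(unknown)[1]]
    ))
  }
  body <- ifelse(is.na(m[, 3]), m[, 4], m[, 3])

  out <- purrr::map2(cls, body, .parse_body)
  res <- dplyr::bind_rows(out)
  res$lipid_class <- cls
  res$species <- format_species(res)
  res[, c(
    "species", "lipid_class", "total_carbons", "total_double_bonds",
    "chains", "isotope_label", "is_internal_standard"
  )]
}

.chain_rx <- "^(C?)(\\d+):(\\d+)(?:-(d\\d+))?$"

.parse_body <- function(cls, body) {
  toks <- stringr::str_trim(stringr::str_split(body, "/")[[1]])
  cm <- stringr::str_match(toks, .chain_rx)
  if (anyNA(cm[, 1])) {
    abort(sprintf("Cannot parse acyl token '%s' in a %s species", toks[which(is.na(cm[, 1]))[1]], cls))
  }
  carbons <- as.integer(cm[, 3])
  db <- as.integer(cm[, 4])
  label <- cm[, 5]
  per_chain <- length(toks) > 1L || any(cm[, 2] == "C")
  if (per_chain) {
    tibble(
      total_carbons = sum(carbons),
      total_double_bonds = sum(db),
      chains = list(tibble(carbons = carbons, double_bonds = db, label = label)),
      isotope_label = NA_character_,
      is_internal_standard = any(!is.na(label))
    )
  } else {
    if (carbons <= 0L) abort(sprintf("Species '%s %s' must have a positive carbon count", cls, body))
    tibble(
      total_carbons = carbons,
      total_double_bonds = db,
      chains = list(NULL),
      isotope_label = label,
      is_internal_standard = !is.na(label)
    )
  }
}

#' Format species to canonical shorthand
#'
#' The inverse of [parse_species()]: per-chain species render as
#' `"CLASS(16:0-d31/18:1)"`, sum compositions as `"CLASS C:D"` with the isotope
#' suffix appended when present. `parse -> format -> parse` round-trips.
#'
#' @param species A tibble as returned by [parse_species()].
#' @return Character vector of canonical names.
#' @export
format_species <- function(species) {
  purrr::pmap_chr(
    list(species$lipid_class, species$total_carbons, species$total_double_bonds,
         species$chains, species$isotope_label),
    function(cls, c, d, ch, lab) {
      if (!is.null(ch)) {
        toks <- sprintf(
          "%d:%d%s", ch$carbons, ch$double_bonds,
          ifelse(is.na(ch$label), "", paste0("-", ch$label))
        )
        sprintf("%s(%s)", cls, paste(toks, collapse = "/"))
      } else {
        sprintf("%s %d:%d%s", cls, c, d, if (is.na(lab)) "" else paste0("-", lab))
      }
    }
  )
}

# deterministic default split of a sum composition into per-chain compositions:
# all but the last chain get floor(C/n) rounded down to an even carbon count,
# the last chain takes the remainder; double bonds are split evenly with the
# excess assigned to the last (longest) chains. Reproduces the common yeast
# pairings, e.g. 32:1 -> 16:0/16:1, 34:1 -> 16:0/18:1, 34:2 -> 16:1/18:1.
.split_sum <- function(cls, carbons, db) {
  n <- .n_chains[[cls]]
  if (carbons < 2L * n) {
    abort(sprintf("Cannot split %s %d:%d into %d chains", cls, carbons, db, n))
  }
  if (n == 1L) {
    cc <- carbons
  } else {
    base <- (carbons %/% n)
    base <- base - (base %% 2L)
    cc <- c(rep(base, n - 1L), carbons - base * (n - 1L))
  }
  dbase <- db %/% n
  dd <- rep(dbase, n)
  extra <- db - dbase * n
  if (extra > 0L) dd[seq.int(n - extra + 1L, n)] <- dd[seq.int(n - extra + 1L, n)] + 1L
  tibble(carbons = as.integer(cc), double_bonds = as.integer(dd), label = NA_character_)
}

#' Default chain-assignment table for yeast sum compositions
#'
#' Measured species are sum compositions (total carbons:double bonds), but
#' both the spontaneous-curvature lookup and the coarse-grained w model need a
#' per-chain unsaturation distribution. This table maps common yeast sum
#' compositions to acyl pairs drawn from the prevalent yeast fatty acids
#' (16:0, 16:1, 18:0, 18:1). It is an implementer convention, not measured
#' ground truth, and can be replaced by any tibble with the same columns.
#'
#' @param carbons Integer vector of total carbon counts to tabulate for
#'   two-chain classes.
#' @param double_bonds Integer vector of total double-bond counts.
#' @return Tibble with columns `lipid_class`, `total_carbons`,
#'   `total_double_bonds`, `chains` (text, e.g. `"16:0/18:1"`).
#' @export
#' @examples
#' default_chain_table() |> head()
default_chain_table <- function(carbons = seq(26L, 40L, by = 2L), double_bonds = 0:4) {
  grid <- tidyr::expand_grid(
    lipid_class = setdiff(lipid_classes(), c("TAG", "CE", "LPC", "SM")),
    total_carbons = as.integer(carbons),
    total_double_bonds = as.integer(double_bonds)
  )
  grid$chains <- purrr::pmap_chr(
    list(grid$lipid_class, grid$total_carbons, grid$total_double_bonds),
    function(cls, c, d) {
      ch <- .split_sum(cls, c, d)
      paste(sprintf("%d:%d", ch$carbons, ch$double_bonds), collapse = "/")
    }
  )
  grid
}

#' Assign per-chain compositions to sum-composition species
#'
#' Species already carrying chains are returned unchanged. For the rest the
#' chain table is consulted first; when no entry exists and `default_rule` is
#' `TRUE`, the deterministic even-split rule behind [default_chain_table()] is
#' applied. The output always satisfies the sum invariants (chain carbons and
#' double bonds add up to the species totals).
#'
#' @param species A tibble as returned by [parse_species()].
#' @param chain_table A chain-assignment table, see [default_chain_table()].
#' @param default_rule Apply the built-in split rule when the table has no
#'   entry? If `FALSE`, unresolved species raise an error listing them.
#' @return `species` with the `chains` list column populated.
#' @export
#' @examples
#' parse_species("PE 34:1") |> assign_chains()
assign_chains <- function(species, chain_table = default_chain_table(), default_rule = TRUE) {
  need <- which(purrr::map_lgl(species$chains, is.null))
  if (length(need) == 0L) return(species)
  key <- function(cls, c, d) paste(cls, c, d)
  tab <- setNames(chain_table$chains, key(
    chain_table$lipid_class, chain_table$total_carbons, chain_table$total_double_bonds
  ))
  new_chains <- purrr::map(need, function(i) {
    cls <- species$lipid_class[i]
    k <- key(cls, species$total_carbons[i], species$total_double_bonds[i])
    if (!is.na(tab[k])) {
      cm <- stringr::str_match(stringr::str_split(tab[[k]], "/")[[1]], .chain_rx)
      tibble(
        carbons = as.integer(cm[, 3]), double_bonds = as.integer(cm[, 4]),
        label = cm[, 5]
      )
    } else if (default_rule) {
      .split_sum(cls, species$total_carbons[i], species$total_double_bonds[i])
    } else {
      abort(sprintf("No chain assignment for species '%s'", species$species[i]))
    }
  })
  bad <- purrr::map_lgl(seq_along(need), function(j) {
    i <- need[j]
    sum(new_chains[[j]]$carbons) != species$total_carbons[i] ||
      sum(new_chains[[j]]$double_bonds) != species$total_double_bonds[i]
  })
  if (any(bad)) {
    abort(sprintf(
      "Chain table entry for '%s' does not sum to its totals",
      species$species[need[which(bad)[1]]]
    ))
  }
  species$chains[need] <- new_chains
  species
}

# parse + chain-assign the distinct species strings of a data column and join
# the parsed fields back on; used by every downstream stage.
.species_info <- function(df, chain_table = NULL, col = "species") {
  uniq <- unique(df[[col]])
  info <- parse_species(uniq)
  if (!is.null(chain_table)) info <- assign_chains(info, chain_table)
  info$.orig <- uniq
  out <- dplyr::left_join(df, dplyr::rename(info, ".orig_species" = ".orig"),
    by = setNames(".orig_species", col), suffix = c("", ".parsed")
  )
  out[[col]] <- out$species.parsed %||% out[[col]]
  out$species.parsed <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
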