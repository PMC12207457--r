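canonical_cols <- c(
  "group_id", "game", "round", "player_id", "treatment_choices",
  "treatment_delegation", "contribution", "public_account_after_round",
  "success", "loss_event", "payoff"
)
# fields recomputable from contributions + the game configuration
derivable_cols <- c("public_account_after_round", "success")

#' Write a study dataset to CSV
#'
#' Emits the canonical long format (one row per group x game x round x
#' player) and, when the study carries delegate programs, a companion
#' tables CSV with one row per (player, game).
#'
#' @param study A study table ([generate_study()] output or compatible).
#' @param path Output CSV path.
#' @param tables_path Optional path for the delegate-table CSV; defaults to
#'   `<path base>_tables.csv` when the study has tables attached.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path, tables_path = NULL) {
  utils::write.csv(as.data.frame(study)[canonical_cols], path,
                   row.names = FALSE)
  tables <- study_tables(study)
  if (!is.null(tables)) {
    if (is.null(tables_path)) {
      tables_path <- sub("(\\.csv)?$", "_tables.csv", path)
    }
    utils::write.csv(as.data.frame(tables), tables_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read and validate a study dataset
#'
#' Reads a long-format CSV into the canonical study table. Foreign schemas
#' are adapted through `column_map`, a named character vector mapping
#' canonical column names to the file's column names; canonical names
#' absent from the map are expected verbatim in the file. The derivable
#' fields (running public account, success) may be missing — they are then
#' recomputed from the contributions and the threshold — and when present
#' they are recomputed anyway and cross-checked: discrepancies are reported
#' as errors with row references, never silently accepted. Structural
#' invariants (complete group x round blocks, contributions inside the
#' treatment's action space, treatments constant within a group, Game 2
#' only for groups with a Game 1) are enforced the same way.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector, canonical -> file
#'   column name.
#' @param tables_path Optional companion delegate-tables CSV.
#' @param threshold,group_size,rounds Game parameters used for validation
#'   and derivation.
#' @return A validated `crd_study` tibble.
#' @export
read_study <- function(path, column_map = NULL, tables_path = NULL,
                       threshold = 80, group_size = 4, rounds = 10) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical_cols)
    if (length(bad)) {
      abort(paste0("unknown canonical columns in `column_map`: ",
                   paste(bad, collapse = ", ")))
    }
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      abort(paste0("columns mapped but absent from file: ",
                   paste(missing_src, collapse = ", ")))
    }
    for (canon in names(column_map)) {
      raw[[canon]] <- raw[[column_map[[canon]]]]
    }
  }
  required <- setdiff(canonical_cols, c(derivable_cols, "loss_event", "payoff"))
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("unmapped required columns: ", paste(missing, collapse = ", ")))
  }
  study <- as_tibble(raw)
  study$treatment_delegation <- as.logical(study$treatment_delegation)

  study <- study |>
    dplyr::arrange(.data$group_id, .data$game, .data$round, .data$player_id) |>
    dplyr::group_by(.data$group_id, .data$game) |>
    dplyr::mutate(
      .derived_pa = {
        rs <- sort(unique(.data$round))
        per_round <- vapply(rs, function(r) {
          sum(.data$contribution[.data$round == r])
        }, numeric(1))
        cumsum(per_round)[match(.data$round, rs)]
      },
      .derived_success = max(.data$.derived_pa) >= threshold
    ) |>
    dplyr::ungroup()

  problems <- character()
  row_ref <- function(idx) paste(utils::head(idx, 5), collapse = ", ")

  space3 <- c(0L, 2L, 4L)
  space5 <- 0:4
  ok_space <- ifelse(study$treatment_choices == 3,
                     study$contribution %in% space3,
                     study$contribution %in% space5)
  if (any(!ok_space)) {
    problems <- c(problems, paste0(
      "contributions outside the treatment's action space at rows: ",
      row_ref(which(!ok_space))
    ))
  }

  blocks <- dplyr::count(study, .data$group_id, .data$game)
  bad_blocks <- blocks$n != group_size * rounds
  if (any(bad_blocks)) {
    problems <- c(problems, paste0(
      "incomplete (group_id, game) blocks (expected ", group_size * rounds,
      " rows): groups ", row_ref(blocks$group_id[bad_blocks])
    ))
  }

  tr_const <- study |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      ok = dplyr::n_distinct(.data$treatment_choices) == 1 &&
        dplyr::n_distinct(.data$treatment_delegation) == 1,
      has_g1 = any(.data$game == 1), has_g2 = any(.data$game == 2)
    )
  if (any(!tr_const$ok)) {
    problems <- c(problems, paste0(
      "treatment labels vary within groups: ",
      row_ref(tr_const$group_id[!tr_const$ok])
    ))
  }
  if (any(tr_const$has_g2 & !tr_const$has_g1)) {
    problems <- c(problems, paste0(
      "Game 2 present without Game 1 for groups: ",
      row_ref(tr_const$group_id[tr_const$has_g2 & !tr_const$has_g1])
    ))
  }

  if ("public_account_after_round" %in% names(study)) {
    mism <- which(study$public_account_after_round != study$.derived_pa)
    if (length(mism)) {
      problems <- c(problems, paste0(
        "public_account_after_round disagrees with the recomputed running ",
        "sum at rows: ", row_ref(mism)
      ))
    }
  } else {
    study$public_account_after_round <- study$.derived_pa
  }
  if ("success" %in% names(study)) {
    mism <- which(as.logical(study$success) != study$.derived_success)
    if (length(mism)) {
      problems <- c(problems, paste0(
        "success flag disagrees with threshold ", threshold,
        " at rows: ", row_ref(mism)
      ))
    }
  } else {
    study$success <- study$.derived_success
  }
  if (length(problems)) {
    abort(paste0("study validation failed:\n- ",
                 paste(problems, collapse = "\n- ")))
  }

  if (!"loss_event" %in% names(study)) study$loss_event <- NA
  if (!"payoff" %in% names(study)) study$payoff <- NA_integer_
  study <- dplyr::select(study, dplyr::all_of(canonical_cols))
  tables <- if (!is.null(tables_path)) {
    as_tibble(utils::read.csv(tables_path, stringsAsFactors = FALSE))
  }
  structure(study, tables = tables, class = c("crd_study", class(study)))
}

#' Read or write a study design as JSON
#'
#' A design file fully specifies a synthetic run: groups per cell, profile
#' mixtures, noise, conditional-table probability, revision parameters and
#' the master seed.
#'
#' @param design A [study_design()].
#' @param path JSON file path.
#' @return `read_design()` returns a [study_design()]; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  jsonlite::write_json(
    list(
      n_groups = design$n_groups,
      mixtures = design$mixtures,
      noise_sd = design$noise_sd,
      p_conditional = design$p_conditional,
      revision = unclass(design$revision),
      seed = design$seed
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  study_design(
    n_groups = x$n_groups,
    mixtures = as_tibble(x$mixtures),
    noise_sd = x$noise_sd,
    p_conditional = x$p_conditional,
    revision = do.call(revision_params, as.list(x$revision)),
    seed = x$seed
  )
}
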