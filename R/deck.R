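# Keyword-deck subset reader/writer. Supported cards: *NODE, *ELEMENT_SOLID,
# *PART, *MAT_SIMPLIFIED_RUBBER/FOAM (alias *MAT_SIMPLIFIED_FOAM),
# *DEFINE_CURVE, *DEFINE_TABLE, *CONTROL_TIMESTEP, *CONTROL_TERMINATION,
# plus the loading extensions *INITIAL_VELOCITY and *RIGIDWALL_PLANAR and
# *DATABASE (output interval). Anything else is preserved verbatim and
# logged, never silently dropped. Both comma-separated and fixed-width
# card dialects are accepted; comment lines start with '$'.

deck_field_widths <- list(
  NODE = c(8, 16, 16, 16),
  ELEMENT_SOLID = rep(8, 10),
  DEFAULT = rep(10, 8)
)

split_card <- function(line, widths) {
  if (grepl(",", line, fixed = TRUE)) {
    out <- strsplit(line, ",", fixed = TRUE)[[1]]
    return(trimws(out))
  }
  # fixed-width cards are right-aligned, so they lead with blanks;
  # free-format cards start in column one and split on whitespace
  if (!grepl("^\\s", line)) {
    return(strsplit(trimws(line), "\\s+")[[1]])
  }
  starts <- cumsum(c(1, widths))
  line <- formatC(line, width = -sum(widths))
  vapply(seq_along(widths), function(i) {
    trimws(substr(line, starts[i], starts[i + 1] - 1))
  }, character(1))
}

card_num <- function(fields, i, default = 0) {
  if (i > length(fields) || !nzchar(fields[i])) return(default)
  x <- suppressWarnings(as.numeric(fields[i]))
  if (is.na(x)) ff_stop("foamfem_malformed_card", "non-numeric field '%s'", fields[i])
  x
}

#' Parse a keyword deck (subset)
#'
#' @param text Either a file path or a character vector of deck lines.
#' @return A `deck` object: data frames `nodes`, `solids`, `parts`,
#'   `materials`; lists `curves`, `tables`; `control` (dtinit, tssfac,
#'   dt2ms, endtim, output_dt); `initial_velocity`; `walls`; and `unknown`
#'   (verbatim unrecognized blocks). A negative `dt2ms` requests selective
#'   mass scaling to `|dt2ms|`; blank means CFL-auto.
#' @export
parse_deck <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text

  deck <- list(nodes = NULL, solids = NULL, parts = NULL, materials = list(),
               curves = list(), tables = list(),
               control = list(dtinit = NA, tssfac = NA, dt2ms = NA,
                              endtim = NA, output_dt = NA),
               initial_velocity = NULL, walls = list(), unknown = list())
  i <- 1L; n <- length(lines)
  current <- NULL; block <- character(0); block_no <- 0L

  flush_block <- function() {
    if (is.null(current)) return(invisible())
    b <- block[!startsWith(trimws(block), "$") & nzchar(trimws(block))]
    kw <- toupper(sub("^\\*", "", current))
    tryCatch(
      deck <<- parse_block(deck, kw, b, current),
      foamfem_malformed_card = function(e) {
        ff_stop("foamfem_malformed_card", "%s (keyword %s near line %d)",
                conditionMessage(e), current, block_no)
      })
    invisible()
  }

  while (i <= n) {
    ln <- lines[i]
    t <- trimws(ln)
    if (startsWith(t, "*")) {
      flush_block()
      current <- t; block <- character(0); block_no <- i
    } else if (!is.null(current)) {
      block <- c(block, ln)
    }
    i <- i + 1L
  }
  flush_block()
  resolve_deck_ids(deck)
  structure(deck, class = "deck")
}

parse_block <- function(deck, kw, b, raw_kw) {
  if (kw %in% c("KEYWORD", "END", "TITLE")) return(deck)
  if (kw == "NODE") {
    rows <- t(vapply(b, function(l) {
      f <- split_card(l, deck_field_widths$NODE)
      c(card_num(f, 1), card_num(f, 2), card_num(f, 3), card_num(f, 4))
    }, numeric(4), USE.NAMES = FALSE))
    nd <- data.frame(id = as.integer(rows[, 1]), x = rows[, 2],
                     y = rows[, 3], z = rows[, 4])
    deck$nodes <- rbind(deck$nodes, nd)
  } else if (kw == "ELEMENT_SOLID") {
    rows <- t(vapply(b, function(l) {
      f <- split_card(l, deck_field_widths$ELEMENT_SOLID)
      vapply(1:10, function(j) card_num(f, j), numeric(1))
    }, numeric(10), USE.NAMES = FALSE))
    sd <- as.data.frame(rows)
    names(sd) <- c("id", "pid", paste0("n", 1:8))
    deck$solids <- rbind(deck$solids, sd)
  } else if (kw == "PART") {
    # heading line, then pid/mid card; repeatable in one block
    j <- 1L
    while (j < length(b)) {
      heading <- trimws(b[j])
      f <- split_card(b[j + 1L], deck_field_widths$DEFAULT)
      deck$parts <- rbind(deck$parts,
                          data.frame(pid = as.integer(card_num(f, 1)),
                                     mid = as.integer(card_num(f, 2)),
                                     heading = heading))
      j <- j + 2L
    }
  } else if (kw %in% c("MAT_SIMPLIFIED_RUBBER/FOAM", "MAT_SIMPLIFIED_FOAM",
                       "MAT_SIMPLIFIED_RUBBER_FOAM")) {
    f1 <- split_card(b[1], deck_field_widths$DEFAULT)
    f2 <- if (length(b) >= 2L) split_card(b[2], deck_field_widths$DEFAULT) else character(0)
    mid <- as.integer(card_num(f1, 1))
    deck$materials[[as.character(mid)]] <- list(
      mid = mid, rho = card_num(f1, 2), km = card_num(f1, 3),
      mu = card_num(f1, 4), g = card_num(f1, 5), sigf = card_num(f1, 6),
      lc = as.integer(card_num(f2, 1)), tbid = as.integer(card_num(f2, 2)),
      sfo = card_num(f2, 3, default = 1), pr = card_num(f2, 4, default = 0.3))
  } else if (kw == "DEFINE_CURVE") {
    f <- split_card(b[1], deck_field_widths$DEFAULT)
    lcid <- as.integer(card_num(f, 1))
    sfa <- card_num(f, 2, default = 1); if (sfa == 0) sfa <- 1
    sfo <- card_num(f, 3, default = 1); if (sfo == 0) sfo <- 1
    pts <- t(vapply(b[-1], function(l) {
      ff <- split_card(l, c(20, 20))
      c(card_num(ff, 1), card_num(ff, 2))
    }, numeric(2), USE.NAMES = FALSE))
    deck$curves[[as.character(lcid)]] <- list(lcid = lcid, sfa = sfa,
                                              sfo = sfo, abscissa = pts[, 1],
                                              ordinate = pts[, 2])
  } else if (kw == "DEFINE_TABLE") {
    f <- split_card(b[1], deck_field_widths$DEFAULT)
    tbid <- as.integer(card_num(f, 1))
    rows <- t(vapply(b[-1], function(l) {
      ff <- split_card(l, c(20, 20))
      c(card_num(ff, 1), card_num(ff, 2))
    }, numeric(2), USE.NAMES = FALSE))
    deck$tables[[as.character(tbid)]] <- list(tbid = tbid, value = rows[, 1],
                                              lcid = as.integer(rows[, 2]))
  } else if (kw == "CONTROL_TIMESTEP") {
    f <- split_card(b[1], deck_field_widths$DEFAULT)
    deck$control$dtinit <- card_num(f, 1, default = NA)
    deck$control$tssfac <- card_num(f, 2, default = NA)
    dt2ms <- if (length(f) >= 3L && nzchar(f[3])) card_num(f, 3) else NA
    deck$control$dt2ms <- dt2ms
  } else if (kw == "CONTROL_TERMINATION") {
    f <- split_card(b[1], deck_field_widths$DEFAULT)
    deck$control$endtim <- card_num(f, 1)
  } else if (kw == "DATABASE") {
    f <- split_card(b[1], deck_field_widths$DEFAULT)
    deck$control$output_dt <- card_num(f, 1)
  } else if (kw == "INITIAL_VELOCITY") {
    f <- split_card(b[1], deck_field_widths$DEFAULT)
    deck$initial_velocity <- c(card_num(f, 1), card_num(f, 2), card_num(f, 3))
  } else if (kw == "RIGIDWALL_PLANAR") {
    f <- split_card(b[1], deck_field_widths$DEFAULT)
    deck$walls[[length(deck$walls) + 1L]] <- list(
      point = c(card_num(f, 1), card_num(f, 2), card_num(f, 3)),
      normal = c(card_num(f, 4), card_num(f, 5), card_num(f, 6)),
      penalty = card_num(f, 7))
  } else {
    ff_log("warn", "ignoring unknown keyword ", raw_kw,
           " (", length(b), " data line(s) preserved verbatim)")
    deck$unknown[[length(deck$unknown) + 1L]] <- c(raw_kw, b)
  }
  deck
}

resolve_deck_ids <- function(deck) {
  for (p in seq_len(NROW(deck$parts))) {
    mid <- as.character(deck$parts$mid[p])
    if (is.null(deck$materials[[mid]])) {
      ff_stop("foamfem_dangling_reference",
              "part %d references missing material %s", deck$parts$pid[p], mid)
    }
  }
  for (m in deck$materials) {
    if (!is.na(m$lc) && m$lc > 0 && is.null(deck$curves[[as.character(m$lc)]])) {
      ff_stop("foamfem_dangling_reference",
              "material %d references missing curve %d", m$mid, m$lc)
    }
    if (!is.na(m$tbid) && m$tbid > 0 && is.null(deck$tables[[as.character(m$tbid)]])) {
      ff_stop("foamfem_dangling_reference",
              "material %d references missing table %d", m$mid, m$tbid)
    }
  }
  for (tb in deck$tables) {
    for (lc in tb$lcid) {
      if (is.null(deck$curves[[as.character(lc)]])) {
        ff_stop("foamfem_dangling_reference",
                "table %d references missing curve %d", tb$tbid, lc)
      }
    }
  }
  if (!is.null(deck$solids) && !is.null(deck$nodes)) {
    if (!all(unlist(deck$solids[paste0("n", 1:8)]) %in% deck$nodes$id)) {
      ff_stop("foamfem_dangling_reference", "solid element references missing node")
    }
  }
  invisible(deck)
}

#' Write a parsed deck back to keyword format
#'
#' Comma-separated dialect; `parse -> write -> parse` is idempotent on the
#' supported subset (unknown blocks are re-emitted verbatim).
#'
#' @param deck A `deck` from [parse_deck()] or [model_to_deck()].
#' @param path Output file path; omit to return the lines invisibly.
#' @return The deck lines, invisibly.
#' @export
write_deck <- function(deck, path = NULL) {
  num <- function(x) trimws(formatC(x, format = "g", digits = 15))
  out <- c("*KEYWORD")
  if (!is.null(deck$nodes)) {
    out <- c(out, "*NODE",
             sprintf("%d,%s,%s,%s", deck$nodes$id, num(deck$nodes$x),
                     num(deck$nodes$y), num(deck$nodes$z)))
  }
  if (!is.null(deck$solids)) {
    out <- c(out, "*ELEMENT_SOLID",
             apply(deck$solids, 1L, function(r) paste(as.integer(r), collapse = ",")))
  }
  for (p in seq_len(NROW(deck$parts))) {
    out <- c(out, "*PART", deck$parts$heading[p],
             sprintf("%d,%d", deck$parts$pid[p], deck$parts$mid[p]))
  }
  for (m in deck$materials) {
    out <- c(out, "*MAT_SIMPLIFIED_RUBBER/FOAM",
             sprintf("%d,%s,%s,%s,%s,%s", m$mid, num(m$rho), num(m$km),
                     num(m$mu), num(m$g), num(m$sigf)),
             sprintf("%d,%d,%s,%s", m$lc, m$tbid, num(m$sfo), num(m$pr)))
  }
  for (cv in deck$curves) {
    out <- c(out, "*DEFINE_CURVE",
             sprintf("%d,%s,%s", cv$lcid, num(cv$sfa), num(cv$sfo)),
             sprintf("%s,%s", num(cv$abscissa), num(cv$ordinate)))
  }
  for (tb in deck$tables) {
    out <- c(out, "*DEFINE_TABLE", sprintf("%d", tb$tbid),
             sprintf("%s,%d", num(tb$value), tb$lcid))
  }
  ctl <- deck$control
  if (!is.na(ctl$dt2ms) || !is.na(ctl$tssfac) || !is.na(ctl$dtinit)) {
    out <- c(out, "*CONTROL_TIMESTEP",
             paste(ifelse(is.na(c(ctl$dtinit, ctl$tssfac, ctl$dt2ms)), "",
                          num(c(ctl$dtinit, ctl$tssfac, ctl$dt2ms))),
                   collapse = ","))
  }
  if (!is.na(ctl$endtim)) {
    out <- c(out, "*CONTROL_TERMINATION", num(ctl$endtim))
  }
  if (!is.na(ctl$output_dt)) {
    out <- c(out, "*DATABASE", num(ctl$output_dt))
  }
  if (!is.null(deck$initial_velocity)) {
    out <- c(out, "*INITIAL_VELOCITY",
             paste(num(deck$initial_velocity), collapse = ","))
  }
  for (w in deck$walls) {
    out <- c(out, "*RIGIDWALL_PLANAR",
             paste(num(c(w$point, w$normal, w$penalty)), collapse = ","))
  }
  for (u in deck$unknown) out <- c(out, u)
  out <- c(out, "*END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Build a runnable model from a parsed deck
#'
#' Converts the deck from its declared unit system (default mm-ms-kg,
#' stresses in GPa) to SI and assembles materials, mesh and configuration.
#' A negative `dt2ms` enables selective mass scaling to `|dt2ms|`; a blank
#' one means CFL-auto stepping.
#'
#' @param deck A `deck` from [parse_deck()].
#' @param units Deck unit system name, see [unit_system()].
#' @param convention Penalty-exponent convention for the materials.
#' @param sfo_override Optional named numeric: part id -> replacement SFO.
#' @return An [fe_model()] ready for [run_simulation()].
#' @export
deck_to_model <- function(deck, units = "mm-ms-kg",
                          convention = c("standard", "paper"),
                          sfo_override = NULL) {
  convention <- match.arg(convention)
  u <- unit_system(units)
  if (is.null(deck$nodes) || is.null(deck$solids)) {
    ff_stop("foamfem_invalid_deck", "deck has no nodes or no solid elements")
  }
  nid <- deck$nodes$id
  remap <- match(as.matrix(deck$solids[paste0("n", 1:8)]), nid)
  conn <- matrix(remap, ncol = 8L)
  mesh <- fe_mesh(as.matrix(deck$nodes[, c("x", "y", "z")]) * u$length,
                  conn, part = as.integer(deck$solids$pid))

  deck_curve <- function(lcid, sfo) {
    cv <- deck$curves[[as.character(lcid)]]
    load_curve(cv$abscissa * cv$sfa, cv$ordinate * u$stress,
               sfo = cv$sfo * sfo)
  }
  materials <- list()
  for (m in deck$materials) {
    sfo <- 1
    if (!is.na(m$tbid) && m$tbid > 0) {
      tb <- deck$tables[[as.character(m$tbid)]]
      tbl <- rate_table(tb$value / u$time,
                        lapply(tb$lcid, function(lc) deck_curve(lc, sfo)))
      mat <- curve_material(tbl, density = m$rho * u$density,
                            K = m$km * u$stress, G = m$g * u$stress,
                            nu = m$pr, mu = m$mu, sigf = m$sigf * u$stress,
                            convention = convention, id = m$mid)
    } else if (!is.na(m$lc) && m$lc > 0) {
      mat <- curve_material(deck_curve(m$lc, sfo), density = m$rho * u$density,
                            K = m$km * u$stress, G = m$g * u$stress,
                            nu = m$pr, mu = m$mu, sigf = m$sigf * u$stress,
                            convention = convention, id = m$mid)
    } else {
      ff_stop("foamfem_invalid_deck", "material %d has neither LC nor TBID", m$mid)
    }
    materials[[as.character(m$mid)]] <- mat
  }

  part_ids <- deck$parts$pid
  part_materials <- stats::setNames(deck$parts$mid, as.character(part_ids))
  if (!is.null(sfo_override)) {
    for (p in names(sfo_override)) {
      mid <- as.character(part_materials[[p]])
      mat <- materials[[mid]]
      src <- mat$curve
      if (inherits(src, "rate_table")) {
        src <- rate_table(src$rates, lapply(src$curves, function(cv) {
          load_curve(cv$strain, cv$stress, sfo = sfo_override[[p]])
        }))
      } else {
        src <- load_curve(src$strain, src$stress, sfo = sfo_override[[p]])
      }
      materials[[mid]] <- curve_material(
        src, density = mat$density, K = mat$K, G = mat$G, nu = mat$nu,
        mu = mat$mu, sigf = mat$sigf, convention = mat$convention, id = mat$id)
    }
  }

  heading_label <- function(h) {
    h <- tolower(h)
    lbl <- c("muscle", "soft", "cortical", "spongy")
    hit <- lbl[vapply(lbl, grepl, logical(1), x = h)]
    if (length(hit)) hit[1] else "other"
  }
  heading_side <- function(h) {
    h <- tolower(h)
    if (grepl("left", h)) "left" else if (grepl("right", h)) "right" else "center"
  }
  part_meta <- data.frame(part = part_ids,
                          label = vapply(deck$parts$heading, heading_label, character(1)),
                          side = vapply(deck$parts$heading, heading_side, character(1)),
                          stringsAsFactors = FALSE)

  ctl <- deck$control
  dt_policy <- "auto"
  if (!is.na(ctl$dt2ms) && ctl$dt2ms != 0) {
    # negative dt2ms means: enable selective mass scaling to |value|
    dt_policy <- list(dt2ms = abs(ctl$dt2ms) * u$time)
  }
  if (is.na(ctl$endtim)) {
    ff_stop("foamfem_invalid_deck", "deck has no termination time")
  }
  safety <- if (!is.na(ctl$tssfac) && ctl$tssfac > 0) ctl$tssfac else 0.9
  cfg <- sim_config(
    termination = ctl$endtim * u$time, dt = dt_policy, safety = safety,
    output_interval = if (!is.na(ctl$output_dt)) ctl$output_dt * u$time else NULL,
    planes = lapply(deck$walls, function(w) {
      rigid_plane(w$point * u$length, w$normal, w$penalty * u$force / u$length)
    }),
    initial_velocity = if (!is.null(deck$initial_velocity)) {
      deck$initial_velocity * u$velocity
    } else NULL)
  fe_model(mesh, materials, part_materials = part_materials,
           part_meta = part_meta, config = cfg)
}

#' Serialize a fixture model to the deck subset
#'
#' Mesh, parts, material card (with its source curve/table), timestep and
#' termination control, plus the initial-velocity and rigid-wall loading
#' extensions. Prescribed motions (the coupon ramp) are outside the deck
#' subset and are dropped with a warning.
#'
#' @param model An [fe_model()].
#' @param units Target deck unit system.
#' @return A `deck` object (write with [write_deck()]).
#' @export
model_to_deck <- function(model, units = "mm-ms-kg") {
  u <- unit_system(units)
  cfg <- model$config
  mesh <- model$mesh
  deck <- list(nodes = data.frame(id = seq_len(nrow(mesh$nodes)),
                                  x = mesh$nodes[, 1] / u$length,
                                  y = mesh$nodes[, 2] / u$length,
                                  z = mesh$nodes[, 3] / u$length),
               solids = cbind(data.frame(id = seq_len(nrow(mesh$elements)),
                                         pid = mesh$part),
                              as.data.frame(mesh$elements) |>
                                stats::setNames(paste0("n", 1:8))),
               parts = NULL, materials = list(), curves = list(),
               tables = list(),
               control = list(dtinit = NA, tssfac = cfg$safety, dt2ms = NA,
                              endtim = cfg$termination / u$time,
                              output_dt = cfg$output_interval / u$time),
               initial_velocity = NULL, walls = list(), unknown = list())
  meta <- model$part_meta
  for (p in sort(unique(mesh$part))) {
    row <- meta[meta$part == p, , drop = FALSE]
    heading <- if (nrow(row)) paste(row$label[1], row$side[1]) else "part"
    deck$parts <- rbind(deck$parts,
                        data.frame(pid = p,
                                   mid = as.integer(model$part_materials[[as.character(p)]]),
                                   heading = heading))
  }
  next_lc <- 1L
  add_curve <- function(cv) {
    id <- next_lc; next_lc <<- next_lc + 1L
    deck$curves[[as.character(id)]] <<- list(
      lcid = id, sfa = 1, sfo = cv$sfo,
      abscissa = cv$strain, ordinate = cv$stress / u$stress)
    id
  }
  for (mat in model$materials) {
    lc <- 0L; tbid <- 0L
    src <- mat$curve
    if (inherits(src, "rate_table")) {
      lcs <- vapply(src$curves, add_curve, integer(1))
      tbid <- length(deck$tables) + 1L
      deck$tables[[as.character(tbid)]] <- list(tbid = tbid,
                                                value = src$rates * unit_system(units)$time,
                                                lcid = lcs)
    } else if (inherits(src, "load_curve")) {
      lc <- add_curve(src)
    } else {
      ff_stop("foamfem_invalid_deck",
              "material %d has no source curve; constants-only cards are not in the deck subset",
              mat$id)
    }
    deck$materials[[as.character(mat$id)]] <- list(
      mid = mat$id, rho = mat$density / u$density, km = mat$K / u$stress,
      mu = mat$mu, g = mat$G / u$stress, sigf = mat$sigf / u$stress,
      lc = lc, tbid = tbid, sfo = 1, pr = mat$nu)
  }
  if (is.list(cfg$dt) && !is.null(cfg$dt$dt2ms)) {
    deck$control$dt2ms <- -cfg$dt$dt2ms / u$time
  }
  if (!is.null(cfg$initial_velocity) && !is.matrix(cfg$initial_velocity)) {
    deck$initial_velocity <- cfg$initial_velocity / u$velocity
  }
  for (pl in cfg$planes) {
    deck$walls[[length(deck$walls) + 1L]] <- list(
      point = pl$point / u$length, normal = pl$normal,
      penalty = pl$penalty / (u$force / u$length))
  }
  if (length(cfg$prescribed)) {
    warning("prescribed motions are outside the deck subset and were dropped")
  }
  structure(deck, class = "deck")
}
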