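# RSML (Root System Markup Language) serialization.
#
# The writer emits one <scene> with one <plant>; root elements are nested
# so that the XML depth encodes the root order. Each root carries a
# polyline geometry and a per-node "diameter" function, plus an
# "insertion_position" property for laterals (curvilinear abscissa on the
# parent, mm). Numbers are printed with %.12g so that a write/read
# round-trip reproduces coordinates to well below 1e-9 mm and identical
# systems produce byte-identical files.

.fmt <- function(v) sprintf("%.12g", v)

.rsml_root_xml <- function(system, i, children_of, id_prefix, indent) {
  r <- system$roots[[i]]
  pad <- strrep("  ", indent)
  lines <- c(sprintf('%s<root id="%s" label="root_%d" po:accession="PO:0009005">',
                     pad, id_prefix, i))
  if (!is.na(r$parent)) {
    lines <- c(lines,
      sprintf('%s  <properties><property name="insertion_position" value="%s"/></properties>',
              pad, .fmt(r$insertion_position_mm)))
  }
  pts <- paste0(pad, "      <point x=\"", .fmt(r$nodes[, "x"]),
                "\" y=\"", .fmt(r$nodes[, "y"]), "\"/>", collapse = "\n")
  smp <- paste0(pad, "      <sample value=\"", .fmt(r$nodes[, "diam"]),
                "\"/>", collapse = "\n")
  lines <- c(lines,
    sprintf("%s  <geometry>", pad),
    sprintf("%s    <polyline>", pad),
    pts,
    sprintf("%s    </polyline>", pad),
    sprintf("%s  </geometry>", pad),
    sprintf("%s  <functions>", pad),
    sprintf('%s    <function name="diameter" domain="polyline">', pad),
    smp,
    sprintf("%s    </function>", pad),
    sprintf("%s  </functions>", pad))
  ch <- children_of[[i]]
  if (!is.null(ch)) {
    for (k in seq_along(ch))
      lines <- c(lines, .rsml_root_xml(system, ch[k],
                                       children_of,
                                       paste0(id_prefix, ".", k),
                                       indent + 1))
  }
  c(lines, sprintf("%s</root>", pad))
}

#' Write a root system to an RSML file
#'
#' @param system a `root_system`.
#' @param destination output file path.
#' @return `destination`, invisibly.
#' @export
write_rsml <- function(system, destination) {
  if (!length(system$roots)) stop("refusing to write a system with no roots")
  roots <- system$roots
  parents <- vapply(roots, function(r)
    if (is.na(r$parent)) 0L else r$parent, 1L)
  children_of <- split(seq_along(roots), parents)
  top <- children_of[["0"]]
  children_of[["0"]] <- NULL
  names(children_of) <- as.character(names(children_of))
  ch_list <- vector("list", length(roots))
  for (nm in names(children_of)) ch_list[[as.integer(nm)]] <- children_of[[nm]]

  body <- character()
  for (k in seq_along(top))
    body <- c(body, .rsml_root_xml(system, top[k], ch_list,
                                   paste0("1.", k), 3))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<rsml xmlns:po="http://www.plantontology.org/xml-dtd/po.dtd">',
    "  <metadata>",
    "    <version>1</version>",
    "    <unit>mm</unit>",
    "    <resolution>1</resolution>",
    "    <software>rootbench</software>",
    sprintf("    <property-definitions/>"),
    "  </metadata>",
    "  <scene>",
    sprintf('    <plant id="1" label="%s">', system$plant_type),
    body,
    "    </plant>",
    "  </scene>",
    "</rsml>")
  ok <- tryCatch({
    con <- suppressWarnings(file(destination, open = "wb"))
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write RSML to '", destination, "': ", conditionMessage(ok))
  invisible(destination)
}

.unit_to_mm <- function(unit) {
  switch(tolower(unit),
         mm = 1, cm = 10, m = 1000, inch = 25.4, um = 1e-3,
         NA_real_)
}

#' Read a root system from an RSML file
#'
#' Reconstructs polylines, per-node diameters, root orders (from XML
#' nesting depth) and parent links. The metadata `unit` is honoured (mm is
#' assumed, with a warning, when absent or unknown); nodes without a
#' diameter annotation get the configured default diameter, with a warning.
#'
#' @param source path to an RSML (XML) file.
#' @param multiple what to do when the scene holds several plants:
#'   `"error"` (default) or `"first"` to keep the first plant only.
#' @param default_diameter_mm diameter assigned when the file carries no
#'   diameter function.
#' @return A `root_system` (with `params = NULL`).
#' @export
read_rsml <- function(source, multiple = c("error", "first"),
                      default_diameter_mm =
                        rootbench_config()$default_diameter_mm) {
  multiple <- match.arg(multiple)
  doc <- xml2::read_xml(source)  # malformed XML errors here
  ns <- xml2::xml_ns_strip(doc)
  unit_node <- xml2::xml_find_first(doc, ".//metadata/unit")
  k <- 1
  if (inherits(unit_node, "xml_missing")) {
    warning("RSML file has no unit; assuming mm")
  } else {
    k <- .unit_to_mm(xml2::xml_text(unit_node))
    if (is.na(k)) {
      warning("unknown RSML unit '", xml2::xml_text(unit_node),
              "'; assuming mm")
      k <- 1
    }
  }
  plants <- xml2::xml_find_all(doc, ".//scene/plant")
  if (!length(plants)) stop("RSML file contains no plant")
  if (length(plants) > 1 && multiple == "error")
    stop("RSML file contains ", length(plants),
         " plants; use multiple = \"first\" to keep the first")
  plant <- plants[[1]]

  roots <- list()
  n <- 0L
  parse_root <- function(node, order, parent_idx) {
    id <- xml2::xml_attr(node, "id")
    pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
    if (!length(pts))
      stop("RSML root '", id, "' has no polyline geometry")
    x <- as.numeric(xml2::xml_attr(pts, "x")) * k
    y <- as.numeric(xml2::xml_attr(pts, "y")) * k
    smp <- xml2::xml_find_all(node,
      "./functions/function[@name='diameter']/sample")
    if (length(smp) == length(x)) {
      d <- as.numeric(xml2::xml_attr(smp, "value")) * k
    } else {
      warning("RSML root '", id, "' has no per-node diameter; using default ",
              default_diameter_mm, " mm")
      d <- rep(default_diameter_mm, length(x))
    }
    ins <- xml2::xml_find_first(node,
      "./properties/property[@name='insertion_position']")
    n <<- n + 1L
    me <- n
    ins_pos <- NA_real_
    if (!is.na(parent_idx)) {
      if (!inherits(ins, "xml_missing")) {
        ins_pos <- as.numeric(xml2::xml_attr(ins, "value")) * k
      } else {
        # nearest-point curvilinear abscissa on the parent polyline
        pn <- roots[[parent_idx]]$nodes
        ins_pos <- .nearest_abscissa(pn[, "x"], pn[, "y"], x[1], y[1])
      }
    }
    roots[[me]] <<- list(nodes = cbind(x = x, y = y, diam = d),
                         order = order, parent = parent_idx,
                         insertion_position_mm = ins_pos)
    for (ch in xml2::xml_find_all(node, "./root"))
      parse_root(ch, order + 1L, me)
  }
  for (top in xml2::xml_find_all(plant, "./root"))
    parse_root(top, 1L, NA_integer_)
  if (!n) stop("RSML plant contains no root elements")
  ptype <- xml2::xml_attr(plant, "label")
  if (is.na(ptype) || !ptype %in% c("fibrous", "tap"))
    ptype <- if (sum(vapply(roots, function(r) r$order, 1L) == 1) > 1)
      "fibrous" else "tap"
  structure(list(roots = roots, plant_type = ptype, params = NULL),
            class = "root_system")
}

# curvilinear abscissa of the nearest point on a polyline
.nearest_abscissa <- function(px, py, qx, qy) {
  if (length(px) < 2) return(0)
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  cum <- c(0, cumsum(seg))
  best <- Inf; best_s <- 0
  for (i in seq_len(length(px) - 1)) {
    dx <- px[i + 1] - px[i]; dy <- py[i + 1] - py[i]
    L2 <- dx^2 + dy^2
    t <- if (L2 > 0) ((qx - px[i]) * dx + (qy - py[i]) * dy) / L2 else 0
    t <- min(max(t, 0), 1)
    d2 <- (px[i] + t * dx - qx)^2 + (py[i] + t * dy - qy)^2
    if (d2 < best) {
      best <- d2
      best_s <- cum[i] + t * seg[i]
    }
  }
  best_s
}
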