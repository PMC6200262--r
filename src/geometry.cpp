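// Planar polygon kernels: shoelace areas, Sutherland-Hodgman clipping against
// convex outlines, even-odd point-in-polygon, raster pixel-center counting,
// and the batched random-placement engine used by the randomization null.
// Coordinates are meters; areas returned in m^2 (converted to ha in R).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<double> dvec;

struct Poly {
  dvec x, y;
  size_t n() const { return x.size(); }
};

static Poly as_poly(const NumericMatrix& m) {
  Poly p;
  int k = m.nrow();
  // drop an explicitly closed last vertex
  if (k > 1 && m(0, 0) == m(k - 1, 0) && m(0, 1) == m(k - 1, 1)) k--;
  p.x.resize(k); p.y.resize(k);
  for (int i = 0; i < k; i++) { p.x[i] = m(i, 0); p.y[i] = m(i, 1); }
  return p;
}

static double signed_area(const Poly& p) {
  double s = 0.0;
  size_t n = p.n();
  if (n < 3) return 0.0;
  for (size_t i = 0; i < n; i++) {
    size_t j = (i + 1) % n;
    s += p.x[i] * p.y[j] - p.x[j] * p.y[i];
  }
  return 0.5 * s;
}

static void centroid(const Poly& p, double& cx, double& cy) {
  double a = 0.0, sx = 0.0, sy = 0.0;
  size_t n = p.n();
  for (size_t i = 0; i < n; i++) {
    size_t j = (i + 1) % n;
    double cr = p.x[i] * p.y[j] - p.x[j] * p.y[i];
    a += cr;
    sx += (p.x[i] + p.x[j]) * cr;
    sy += (p.y[i] + p.y[j]) * cr;
  }
  a *= 0.5;
  if (std::fabs(a) < 1e-12) { // degenerate: vertex mean
    cx = 0; cy = 0;
    for (size_t i = 0; i < n; i++) { cx += p.x[i]; cy += p.y[i]; }
    cx /= n; cy /= n;
  } else {
    cx = sx / (6.0 * a); cy = sy / (6.0 * a);
  }
}

static bool point_in_poly(double px, double py, const Poly& p) {
  // even-odd ray casting
  bool inside = false;
  size_t n = p.n();
  for (size_t i = 0, j = n - 1; i < n; j = i++) {
    if (((p.y[i] > py) != (p.y[j] > py)) &&
        (px < (p.x[j] - p.x[i]) * (py - p.y[i]) / (p.y[j] - p.y[i]) + p.x[i]))
      inside = !inside;
  }
  return inside;
}

static void ensure_ccw(Poly& p) {
  if (signed_area(p) < 0) {
    std::reverse(p.x.begin(), p.x.end());
    std::reverse(p.y.begin(), p.y.end());
  }
}

// Sutherland-Hodgman: clip `subj` (any simple polygon) against convex `clip`.
// Returns |area| of the intersection (correct for simple subjects even when
// the output carries zero-width bridges).
static double clip_area(const Poly& subj, Poly clip) {
  if (subj.n() < 3 || clip.n() < 3) return 0.0;
  ensure_ccw(clip);
  dvec sx = subj.x, sy = subj.y;
  size_t nc = clip.n();
  for (size_t e = 0; e < nc && sx.size() >= 3; e++) {
    size_t f = (e + 1) % nc;
    double ax = clip.x[e], ay = clip.y[e], bx = clip.x[f], by = clip.y[f];
    double ex = bx - ax, ey = by - ay;
    dvec ox, oy;
    size_t n = sx.size();
    for (size_t i = 0; i < n; i++) {
      size_t j = (i + 1) % n;
      double d1 = ex * (sy[i] - ay) - ey * (sx[i] - ax); // >=0: inside (left)
      double d2 = ex * (sy[j] - ay) - ey * (sx[j] - ax);
      bool in1 = d1 >= 0, in2 = d2 >= 0;
      if (in1) { ox.push_back(sx[i]); oy.push_back(sy[i]); }
      if (in1 != in2) {
        double t = d1 / (d1 - d2);
        ox.push_back(sx[i] + t * (sx[j] - sx[i]));
        oy.push_back(sy[i] + t * (sy[j] - sy[i]));
      }
    }
    sx.swap(ox); sy.swap(oy);
  }
  if (sx.size() < 3) return 0.0;
  Poly out; out.x = sx; out.y = sy;
  return std::fabs(signed_area(out));
}

static bool is_convex(const Poly& p) {
  size_t n = p.n();
  if (n < 3) return false;
  int sign = 0;
  for (size_t i = 0; i < n; i++) {
    size_t j = (i + 1) % n, k = (i + 2) % n;
    double cr = (p.x[j] - p.x[i]) * (p.y[k] - p.y[j]) -
                (p.y[j] - p.y[i]) * (p.x[k] - p.x[j]);
    if (std::fabs(cr) < 1e-12) continue;
    int s = cr > 0 ? 1 : -1;
    if (sign == 0) sign = s; else if (s != sign) return false;
  }
  return true;
}

// [[Rcpp::export]]
double poly_area_cpp(NumericMatrix m) {
  return std::fabs(signed_area(as_poly(m)));
}

// [[Rcpp::export]]
NumericVector poly_centroid_cpp(NumericMatrix m) {
  double cx, cy;
  centroid(as_poly(m), cx, cy);
  return NumericVector::create(cx, cy);
}

// [[Rcpp::export]]
bool is_convex_cpp(NumericMatrix m) {
  return is_convex(as_poly(m));
}

// [[Rcpp::export]]
double clip_area_cpp(NumericMatrix subject, NumericMatrix clip) {
  return clip_area(as_poly(subject), as_poly(clip));
}

// [[Rcpp::export]]
LogicalVector points_in_poly_cpp(NumericVector px, NumericVector py,
                                 NumericMatrix poly) {
  Poly p = as_poly(poly);
  int n = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = point_in_poly(px[i], py[i], p);
  return out;
}

// membership in the union of a set of polygons
// [[Rcpp::export]]
LogicalVector points_in_polys_cpp(NumericVector px, NumericVector py,
                                  List polys) {
  int np = polys.size(), n = px.size();
  std::vector<Poly> ps(np);
  for (int k = 0; k < np; k++) ps[k] = as_poly(as<NumericMatrix>(polys[k]));
  LogicalVector out(n);
  for (int i = 0; i < n; i++) {
    bool in = false;
    for (int k = 0; k < np && !in; k++) in = point_in_poly(px[i], py[i], ps[k]);
    out[i] = in;
  }
  return out;
}

// Raster dialect: count pixels whose center falls in the union of outline
// polygons, per category code. `codes` lists the codes to tally (grid values
// not in `codes` are ignored). Grid value grid(r, c) sits at center
// (x0 + (c + 0.5) * ps, y0 + (r + 0.5) * ps) with row 0 the southernmost.
// [[Rcpp::export]]
NumericVector raster_zone_counts_cpp(IntegerMatrix grid, double x0, double y0,
                                     double ps, List outline,
                                     IntegerVector codes) {
  int np = outline.size();
  std::vector<Poly> ps_out(np);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int k = 0; k < np; k++) {
    ps_out[k] = as_poly(as<NumericMatrix>(outline[k]));
    for (size_t i = 0; i < ps_out[k].n(); i++) {
      xmin = std::min(xmin, ps_out[k].x[i]); xmax = std::max(xmax, ps_out[k].x[i]);
      ymin = std::min(ymin, ps_out[k].y[i]); ymax = std::max(ymax, ps_out[k].y[i]);
    }
  }
  std::map<int, int> idx;
  for (int j = 0; j < codes.size(); j++) idx[codes[j]] = j;
  NumericVector counts(codes.size());
  int nr = grid.nrow(), nc = grid.ncol();
  int c0 = std::max(0, (int)std::floor((xmin - x0) / ps - 0.5));
  int c1 = std::min(nc - 1, (int)std::ceil((xmax - x0) / ps));
  int r0 = std::max(0, (int)std::floor((ymin - y0) / ps - 0.5));
  int r1 = std::min(nr - 1, (int)std::ceil((ymax - y0) / ps));
  for (int r = r0; r <= r1; r++) {
    double cy = y0 + (r + 0.5) * ps;
    for (int c = c0; c <= c1; c++) {
      int g = grid(r, c);
      if (g == NA_INTEGER) continue;
      std::map<int, int>::iterator it = idx.find(g);
      if (it == idx.end()) continue;
      double cx = x0 + (c + 0.5) * ps;
      bool in = false;
      for (int k = 0; k < np && !in; k++) in = point_in_poly(cx, cy, ps_out[k]);
      if (in) counts[it->second] += 1.0;
    }
  }
  return counts;
}

// Vector dialect: exact intersection areas (m^2) of an outline (list of
// disjoint CONVEX polygons) with categorised patches, per code in `codes`.
// [[Rcpp::export]]
NumericVector vector_zone_areas_cpp(List outline, List patches,
                                    IntegerVector patch_code,
                                    IntegerVector codes) {
  int np = outline.size(), npat = patches.size();
  std::vector<Poly> outs(np);
  for (int k = 0; k < np; k++) outs[k] = as_poly(as<NumericMatrix>(outline[k]));
  std::map<int, int> idx;
  for (int j = 0; j < codes.size(); j++) idx[codes[j]] = j;
  NumericVector area(codes.size());
  for (int p = 0; p < npat; p++) {
    std::map<int, int>::iterator it = idx.find(patch_code[p]);
    if (it == idx.end()) continue;
    Poly pat = as_poly(as<NumericMatrix>(patches[p]));
    for (int k = 0; k < np; k++) area[it->second] += clip_area(pat, outs[k]);
  }
  return area;
}

struct FlatOutline {
  std::vector<Poly> polys;
  double cx, cy, area;
};

static void bbox_of(const std::vector<Poly>& ps, double& xmin, double& xmax,
                    double& ymin, double& ymax) {
  xmin = ymin = R_PosInf; xmax = ymax = R_NegInf;
  for (size_t k = 0; k < ps.size(); k++)
    for (size_t i = 0; i < ps[k].n(); i++) {
      xmin = std::min(xmin, ps[k].x[i]); xmax = std::max(xmax, ps[k].x[i]);
      ymin = std::min(ymin, ps[k].y[i]); ymax = std::max(ymax, ps[k].y[i]);
    }
}

// Batched randomization engine (vector maps). Each replicate draws I outlines
// with replacement, rotates each by U(0, 2pi) about its area centroid and
// displaces it so the centroid falls uniformly in `hull` (rejection sampling
// from the hull bounding box). Uses R's RNG so results are reproducible under
// set.seed(). require_code >= 0 re-places an outline (up to max_try) until
// that code's area is positive; first-throw presence is recorded before any
// re-placement. contained=true additionally rejects placements with vertices
// outside `extent` (xmin, xmax, ymin, ymax).
// [[Rcpp::export]]
List randomize_batch_cpp(List outlines, List patches, IntegerVector patch_code,
                         IntegerVector codes, NumericMatrix hull, int n_rand,
                         int require_code, bool contained,
                         NumericVector extent, int max_try) {
  int I = outlines.size(), J = codes.size();
  std::vector<FlatOutline> fo(I);
  for (int i = 0; i < I; i++) {
    List li = outlines[i];
    fo[i].polys.resize(li.size());
    double atot = 0, sx = 0, sy = 0;
    for (int k = 0; k < li.size(); k++) {
      fo[i].polys[k] = as_poly(as<NumericMatrix>(li[k]));
      double a = std::fabs(signed_area(fo[i].polys[k]));
      double cx, cy; centroid(fo[i].polys[k], cx, cy);
      atot += a; sx += a * cx; sy += a * cy;
    }
    fo[i].area = atot;
    fo[i].cx = atot > 0 ? sx / atot : 0;
    fo[i].cy = atot > 0 ? sy / atot : 0;
  }
  int npat = patches.size();
  std::vector<Poly> pat(npat);
  for (int p = 0; p < npat; p++) pat[p] = as_poly(as<NumericMatrix>(patches[p]));
  std::map<int, int> idx;
  for (int j = 0; j < J; j++) idx[codes[j]] = j;
  int req = -1;
  if (require_code != NA_INTEGER && require_code >= 0) {
    std::map<int, int>::iterator it = idx.find(require_code);
    if (it != idx.end()) req = it->second;
  }
  Poly hp = as_poly(hull);
  double hx0, hx1, hy0, hy1;
  {
    std::vector<Poly> hv(1, hp);
    bbox_of(hv, hx0, hx1, hy0, hy1);
  }
  NumericMatrix A(n_rand, I);
  NumericVector cube(n_rand * I * J); // [rep, animal, code]
  NumericMatrix first_present(n_rand, J);
  IntegerMatrix draw(n_rand, I);
  std::vector<Poly> placed;
  for (int rep = 0; rep < n_rand; rep++) {
    for (int i = 0; i < I; i++) {
      int d = (int)std::floor(unif_rand() * I);
      if (d >= I) d = I - 1;
      draw(rep, i) = d + 1;
      A(rep, i) = fo[d].area;
      dvec aj(J, 0.0);
      for (int attempt = 0; attempt < max_try; attempt++) {
        // rotation + displacement
        double th = unif_rand() * 2.0 * M_PI;
        double ct = std::cos(th), st = std::sin(th);
        double px = 0, py = 0;
        bool ok = false;
        for (int t = 0; t < 10000; t++) {
          px = hx0 + unif_rand() * (hx1 - hx0);
          py = hy0 + unif_rand() * (hy1 - hy0);
          if (point_in_poly(px, py, hp)) { ok = true; break; }
        }
        if (!ok) stop("could not sample a point inside the study hull");
        placed.assign(fo[d].polys.begin(), fo[d].polys.end());
        bool inside_extent = true;
        for (size_t k = 0; k < placed.size(); k++) {
          for (size_t v = 0; v < placed[k].n(); v++) {
            double dx = placed[k].x[v] - fo[d].cx, dy = placed[k].y[v] - fo[d].cy;
            double nx = px + ct * dx - st * dy;
            double ny = py + st * dx + ct * dy;
            placed[k].x[v] = nx; placed[k].y[v] = ny;
            if (contained &&
                (nx < extent[0] || nx > extent[1] || ny < extent[2] || ny > extent[3]))
              inside_extent = false;
          }
        }
        if (contained && !inside_extent) continue;
        std::fill(aj.begin(), aj.end(), 0.0);
        for (int p = 0; p < npat; p++) {
          std::map<int, int>::iterator it = idx.find(patch_code[p]);
          if (it == idx.end()) continue;
          for (size_t k = 0; k < placed.size(); k++)
            aj[it->second] += clip_area(pat[p], placed[k]);
        }
        if (attempt == 0)
          for (int j = 0; j < J; j++)
            if (aj[j] > 0) first_present(rep, j) += 1.0;
        if (req < 0 || aj[req] > 0) break;
      }
      for (int j = 0; j < J; j++)
        cube[rep + n_rand * (i + (R_xlen_t)I * j)] = aj[j];
    }
  }
  return List::create(_["A"] = A, _["areas"] = cube,
                      _["first_present"] = first_present, _["draw"] = draw);
}
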