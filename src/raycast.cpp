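#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection. Returns t > tmin on hit, -1 otherwise.
static inline double ray_tri(const double* o, const double* d,
                             const double* a, const double* b, const double* c,
                             double tmin) {
  double e1[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double e2[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double p[3]  = { d[1]*e2[2]-d[2]*e2[1], d[2]*e2[0]-d[0]*e2[2], d[0]*e2[1]-d[1]*e2[0] };
  double det = e1[0]*p[0] + e1[1]*p[1] + e1[2]*p[2];
  if (std::fabs(det) < 1e-14) return -1.0;
  double inv = 1.0 / det;
  double s[3] = { o[0]-a[0], o[1]-a[1], o[2]-a[2] };
  double u = (s[0]*p[0] + s[1]*p[1] + s[2]*p[2]) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return -1.0;
  double q[3] = { s[1]*e1[2]-s[2]*e1[1], s[2]*e1[0]-s[0]*e1[2], s[0]*e1[1]-s[1]*e1[0] };
  double v = (d[0]*q[0] + d[1]*q[1] + d[2]*q[2]) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return -1.0;
  double t = (e2[0]*q[0] + e2[1]*q[1] + e2[2]*q[2]) * inv;
  if (t <= tmin) return -1.0;
  return t;
}

// First-hit ray casting of a ray bundle from a common origin against a triangle
// soup. Faces are binned on a gnomonic (tangent-plane) grid spanned by the
// camera frame (u, v, w = view direction): central projection maps triangles to
// triangles, so the vertex bounding box in tangent coordinates bounds the
// projected triangle and binning is conservative. Faces touching the camera
// plane fall back to per-ray testing.
// [[Rcpp::export]]
List cpp_first_hit(NumericVector origin, NumericMatrix dirs,
                   NumericMatrix V, IntegerMatrix F, IntegerVector mesh_id,
                   NumericVector u_axis, NumericVector v_axis, NumericVector w_axis) {
  const int nray = dirs.nrow(), nf = F.nrow();
  const double o[3] = { origin[0], origin[1], origin[2] };

  std::vector<double> tu(nray), tv(nray);
  double tu_min = R_PosInf, tu_max = R_NegInf, tv_min = R_PosInf, tv_max = R_NegInf;
  for (int r = 0; r < nray; ++r) {
    double dw = dirs(r,0)*w_axis[0] + dirs(r,1)*w_axis[1] + dirs(r,2)*w_axis[2];
    double du = dirs(r,0)*u_axis[0] + dirs(r,1)*u_axis[1] + dirs(r,2)*u_axis[2];
    double dv = dirs(r,0)*v_axis[0] + dirs(r,1)*v_axis[1] + dirs(r,2)*v_axis[2];
    if (dw <= 1e-9) stop("ray direction outside the forward hemisphere of the camera");
    tu[r] = du / dw; tv[r] = dv / dw;
    tu_min = std::min(tu_min, tu[r]); tu_max = std::max(tu_max, tu[r]);
    tv_min = std::min(tv_min, tv[r]); tv_max = std::max(tv_max, tv[r]);
  }
  const double pad = 1e-9;
  tu_min -= pad; tu_max += pad; tv_min -= pad; tv_max += pad;
  int nb = std::max(1, (int)std::floor(std::sqrt((double)nray)));
  nb = std::min(nb, 128);
  const double su = (tu_max - tu_min) / nb, sv = (tv_max - tv_min) / nb;

  std::vector< std::vector<int> > bins((size_t)nb * nb);
  std::vector<int> fallback;
  for (int f = 0; f < nf; ++f) {
    double fu_min = R_PosInf, fu_max = R_NegInf, fv_min = R_PosInf, fv_max = R_NegInf;
    bool bad = false;
    for (int k = 0; k < 3; ++k) {
      int vi = F(f,k);
      double x = V(vi,0)-o[0], y = V(vi,1)-o[1], z = V(vi,2)-o[2];
      double xw = x*w_axis[0] + y*w_axis[1] + z*w_axis[2];
      if (xw <= 1e-9) { bad = true; break; }
      double xu = (x*u_axis[0] + y*u_axis[1] + z*u_axis[2]) / xw;
      double xv = (x*v_axis[0] + y*v_axis[1] + z*v_axis[2]) / xw;
      fu_min = std::min(fu_min, xu); fu_max = std::max(fu_max, xu);
      fv_min = std::min(fv_min, xv); fv_max = std::max(fv_max, xv);
    }
    if (bad) { fallback.push_back(f); continue; }
    if (fu_max < tu_min || fu_min > tu_max || fv_max < tv_min || fv_min > tv_max) continue;
    int i0 = std::max(0, (int)std::floor((fu_min - tu_min) / su));
    int i1 = std::min(nb - 1, (int)std::floor((fu_max - tu_min) / su));
    int j0 = std::max(0, (int)std::floor((fv_min - tv_min) / sv));
    int j1 = std::min(nb - 1, (int)std::floor((fv_max - tv_min) / sv));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        bins[(size_t)i * nb + j].push_back(f);
  }

  LogicalVector hit(nray);
  NumericVector tt(nray), px(nray), py(nray), pz(nray), nx(nray), ny(nray), nz(nray);
  IntegerVector mid(nray), fid(nray);
  std::vector<double> dbuf(3);
  for (int r = 0; r < nray; ++r) {
    double d[3] = { dirs(r,0), dirs(r,1), dirs(r,2) };
    int bi = std::min(nb - 1, std::max(0, (int)std::floor((tu[r] - tu_min) / su)));
    int bj = std::min(nb - 1, std::max(0, (int)std::floor((tv[r] - tv_min) / sv)));
    const std::vector<int>& cand = bins[(size_t)bi * nb + bj];
    double best = R_PosInf; int bestf = -1;
    for (size_t c = 0; c < cand.size() + fallback.size(); ++c) {
      int f = (c < cand.size()) ? cand[c] : fallback[c - cand.size()];
      int i0 = F(f,0), i1 = F(f,1), i2 = F(f,2);
      double a[3] = { V(i0,0), V(i0,1), V(i0,2) };
      double b[3] = { V(i1,0), V(i1,1), V(i1,2) };
      double cc[3] = { V(i2,0), V(i2,1), V(i2,2) };
      double t = ray_tri(o, d, a, b, cc, 1e-8);
      if (t > 0 && t < best) { best = t; bestf = f; }
    }
    if (bestf < 0) { hit[r] = false; continue; }
    hit[r] = true; tt[r] = best;
    px[r] = o[0] + best*d[0]; py[r] = o[1] + best*d[1]; pz[r] = o[2] + best*d[2];
    int i0 = F(bestf,0), i1 = F(bestf,1), i2 = F(bestf,2);
    double e1[3] = { V(i1,0)-V(i0,0), V(i1,1)-V(i0,1), V(i1,2)-V(i0,2) };
    double e2[3] = { V(i2,0)-V(i0,0), V(i2,1)-V(i0,1), V(i2,2)-V(i0,2) };
    double n[3] = { e1[1]*e2[2]-e1[2]*e2[1], e1[2]*e2[0]-e1[0]*e2[2], e1[0]*e2[1]-e1[1]*e2[0] };
    double nn = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    if (nn > 0) { n[0] /= nn; n[1] /= nn; n[2] /= nn; }
    nx[r] = n[0]; ny[r] = n[1]; nz[r] = n[2];
    mid[r] = mesh_id[bestf]; fid[r] = bestf + 1;
  }
  return List::create(_["hit"] = hit, _["t"] = tt,
                      _["px"] = px, _["py"] = py, _["pz"] = pz,
                      _["nx"] = nx, _["ny"] = ny, _["nz"] = nz,
                      _["mesh"] = mid, _["face"] = fid);
}
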