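#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Binary STL (little-endian, mm units): 80-byte header, uint32 facet count,
// then 50-byte records (normal 3f, vertices 9f, uint16 attribute).

// [[Rcpp::export]]
void cpp_write_stl_binary(std::string path, NumericMatrix V, IntegerMatrix F) {
  FILE *fp = std::fopen(path.c_str(), "wb");
  if (!fp) stop("cannot open '%s' for writing", path.c_str());
  char header[80];
  std::memset(header, 0, 80);
  std::snprintf(header, 80, "binary STL, units mm");
  std::fwrite(header, 1, 80, fp);
  uint32_t nf = (uint32_t)F.nrow();
  std::fwrite(&nf, 4, 1, fp);
  std::vector<char> rec(50);
  for (uint32_t f = 0; f < nf; ++f) {
    int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    float ax = (float)V(a,0), ay = (float)V(a,1), az = (float)V(a,2);
    float bx = (float)V(b,0), by = (float)V(b,1), bz = (float)V(b,2);
    float cx = (float)V(c,0), cy = (float)V(c,1), cz = (float)V(c,2);
    float ux = bx-ax, uy = by-ay, uz = bz-az;
    float vx = cx-ax, vy = cy-ay, vz = cz-az;
    float nx = uy*vz-uz*vy, ny = uz*vx-ux*vz, nz = ux*vy-uy*vx;
    float l = std::sqrt(nx*nx+ny*ny+nz*nz);
    if (l > 0) { nx /= l; ny /= l; nz /= l; }
    float vals[12] = {nx,ny,nz, ax,ay,az, bx,by,bz, cx,cy,cz};
    std::memcpy(rec.data(), vals, 48);
    uint16_t attr = 0;
    std::memcpy(rec.data()+48, &attr, 2);
    std::fwrite(rec.data(), 1, 50, fp);
  }
  std::fclose(fp);
}

// [[Rcpp::export]]
NumericMatrix cpp_read_stl_binary(std::string path) {
  FILE *fp = std::fopen(path.c_str(), "rb");
  if (!fp) stop("cannot open '%s'", path.c_str());
  char header[80];
  if (std::fread(header, 1, 80, fp) != 80) {
    std::fclose(fp);
    stop("truncated STL: header ends before byte 80");
  }
  uint32_t nf;
  if (std::fread(&nf, 4, 1, fp) != 1) {
    std::fclose(fp);
    stop("truncated STL: facet count missing at byte 80");
  }
  NumericMatrix tris(nf, 9);
  std::vector<char> rec(50);
  for (uint32_t f = 0; f < nf; ++f) {
    if (std::fread(rec.data(), 1, 50, fp) != 50) {
      long off = std::ftell(fp);
      std::fclose(fp);
      stop("truncated STL: facet %u incomplete near byte offset %ld",
           (unsigned)f, off);
    }
    float vals[12];
    std::memcpy(vals, rec.data(), 48);
    for (int c = 0; c < 9; ++c) tris(f, c) = (double)vals[c + 3];
  }
  // extra trailing bytes mean the header count disagrees with the file length
  char probe;
  if (std::fread(&probe, 1, 1, fp) == 1) {
    std::fclose(fp);
    stop("STL facet count in header inconsistent with file length");
  }
  std::fclose(fp);
  return tris;
}
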